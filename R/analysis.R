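#' Euclidean dissimilarity matrix on site features
#'
#' Computes pairwise Euclidean distances on (optionally standardized)
#' per-site feature vectors.  Standardization defaults on because typical
#' feature sets mix units (degrees C, mm, days).  Sites with any missing
#' feature are excluded and reported; zero-variance features are dropped
#' under standardization with a warning.
#'
#' @param features Numeric data.frame or matrix, one row per site; row
#'   names (or a `site_id` column) identify sites.
#' @param standardize Z-score each feature first (default `TRUE`).
#' @return A `dist` object; excluded site ids are in the
#'   `excluded_sites` attribute.
#' @export
dissimilarity_matrix <- function(features, standardize = TRUE) {
  if (is.data.frame(features) && "site_id" %in% names(features)) {
    rownames(features) <- as.character(features$site_id)
    features$site_id <- NULL
  }
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  excluded <- rownames(m)[apply(m, 1, anyNA)]
  if (length(excluded) > 0) {
    warning("dissimilarity_matrix: excluding ", length(excluded),
            " site(s) with missing features: ",
            paste(excluded, collapse = ", "))
    m <- m[!rownames(m) %in% excluded, , drop = FALSE]
  }
  if (nrow(m) < 2) stop("dissimilarity_matrix: need at least 2 complete sites")
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    zero <- sds == 0 | !is.finite(sds)
    if (any(zero)) {
      warning("dissimilarity_matrix: dropping zero-variance feature(s): ",
              paste(colnames(m)[zero], collapse = ", "))
      m <- m[, !zero, drop = FALSE]
      sds <- sds[!zero]
    }
    if (ncol(m) == 0) stop("dissimilarity_matrix: no usable features remain")
    m <- scale(m)
  }
  d <- stats::dist(m, method = "euclidean")
  attr(d, "excluded_sites") <- excluded
  d
}

# Total cost of a medoid set: sum over points of distance to nearest medoid.
.pam_cost <- function(dm, medoids) {
  sum(apply(dm[, medoids, drop = FALSE], 1, min))
}

#' Partitioning around medoids (PAM)
#'
#' k-medoids on a precomputed distance matrix.  Tiny instances (at most
#' `exact_limit` candidate medoid sets) are solved exactly by enumerating
#' every medoid subset, which sidesteps the known local optima of the
#' swap neighborhood; larger instances use classic BUILD + SWAP: BUILD
#' greedily picks medoids that most reduce the total
#' distance-to-nearest-medoid cost, then SWAP repeatedly applies the
#' single best improving medoid/non-medoid exchange until no exchange
#' lowers the cost.  Either way the run is deterministic: ties (in cost
#' and in nearest-medoid assignment) break toward the lowest row index,
#' so row order is the only tie-break rule.
#'
#' @param dist A `dist` object or symmetric distance matrix.
#' @param k Number of clusters, 2 <= k < n.
#' @param seed Integer recorded in the model for provenance; the algorithm
#'   itself is deterministic and does not consume randomness.
#' @param exact_limit Enumerate all medoid sets exactly when
#'   `choose(n, k)` does not exceed this (default 5000).
#' @return An object of class `cluster_model`: list with `k`,
#'   `medoid_ids`, `assignment` (named integer vector, site -> cluster),
#'   `avg_silhouette`, `cost`, `variables_used`, `seed`.
#' @export
pam_cluster <- function(dist, k, seed = 1L, exact_limit = 5000) {
  dm <- as.matrix(dist)
  n <- nrow(dm)
  ids <- rownames(dm)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (k < 2 || k >= n) stop("pam_cluster: need 2 <= k < n (n = ", n, ")")

  if (choose(n, k) <= exact_limit) {
    # exact: global minimum over every candidate medoid set; combn order
    # makes the lexicographically first optimum the deterministic winner
    combos <- utils::combn(n, k)
    costs <- apply(combos, 2, function(med) .pam_cost(dm, med))
    medoids <- combos[, which.min(costs)]
  } else {
    # BUILD: first medoid minimizes total distance; then greedy additions.
    medoids <- which.min(colSums(dm))
    while (length(medoids) < k) {
      nearest <- apply(dm[, medoids, drop = FALSE], 1, min)
      cand <- setdiff(seq_len(n), medoids)
      gains <- vapply(cand, function(j) sum(pmax(nearest - dm[, j], 0)),
                      numeric(1))
      medoids <- c(medoids, cand[which.max(gains)])
    }

    # SWAP: accept the best improving exchange until none improves.
    cost <- .pam_cost(dm, medoids)
    repeat {
      best_delta <- 0
      best_swap <- NULL
      for (m in medoids) {
        for (h in setdiff(seq_len(n), medoids)) {
          trial <- c(setdiff(medoids, m), h)
          delta <- .pam_cost(dm, trial) - cost
          if (delta < best_delta - 1e-12) {
            best_delta <- delta
            best_swap <- c(m, h)
          }
        }
      }
      if (is.null(best_swap)) break
      medoids <- c(setdiff(medoids, best_swap[1]), best_swap[2])
      cost <- cost + best_delta
    }
  }

  medoids <- sort(medoids)
  assignment <- apply(dm[, medoids, drop = FALSE], 1, which.min)
  names(assignment) <- ids
  sil <- silhouette_widths(dm, assignment)
  structure(list(
    k = as.integer(k), medoid_ids = ids[medoids],
    assignment = assignment, avg_silhouette = mean(sil),
    cost = .pam_cost(dm, medoids), variables_used = character(0),
    seed = as.integer(seed)
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("PAM cluster model: k = %d, cost = %.4g, avg silhouette = %.3f\n",
              x$k, x$cost, x$avg_silhouette))
  cat("  medoids:", paste(x$medoid_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Per-point silhouette widths
#'
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)) with a(i) the mean distance of i
#' to the other members of its own cluster and b(i) the smallest mean
#' distance to any other cluster.  Points in singleton clusters get 0.
#'
#' @param dist A `dist` object or symmetric distance matrix.
#' @param assignment Integer cluster labels, one per point.
#' @return Numeric vector of silhouette widths in [-1, 1].
#' @export
silhouette_widths <- function(dist, assignment) {
  dm <- as.matrix(dist)
  n <- nrow(dm)
  stopifnot(length(assignment) == n)
  ks <- sort(unique(assignment))
  vapply(seq_len(n), function(i) {
    own <- assignment[i]
    own_members <- which(assignment == own)
    if (length(own_members) == 1L) return(0)
    a <- mean(dm[i, setdiff(own_members, i)])
    b <- min(vapply(setdiff(ks, own), function(kk) {
      mean(dm[i, assignment == kk])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

#' Select the number of clusters by average silhouette width
#'
#' Runs [pam_cluster()] for each candidate k and returns the model with the
#' highest average silhouette width (ties break toward smaller k).  The
#' per-k summary is attached as the `k_summary` attribute.
#'
#' @param dist A `dist` object or symmetric distance matrix.
#' @param k_range Integer vector of candidate cluster counts within
#'   [2, n-1].
#' @param seed Passed to [pam_cluster()].
#' @return The winning `cluster_model`; `attr(, "k_summary")` is a
#'   data.frame of k and avg_silhouette.
#' @export
select_k <- function(dist, k_range, seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop("select_k: empty k_range")
  n <- attr(stats::as.dist(as.matrix(dist)), "Size")
  if (any(k_range < 2 | k_range >= n)) {
    stop("select_k: k_range must lie within [2, n-1]")
  }
  models <- lapply(k_range, function(k) pam_cluster(dist, k, seed))
  sil <- vapply(models, `[[`, numeric(1), "avg_silhouette")
  best <- models[[which.max(sil)]]
  attr(best, "k_summary") <- data.frame(k = k_range, avg_silhouette = sil)
  best
}

#' Group-wise squared Pearson correlation of eFit against observed tNpp
#'
#' For each level of a grouping label (climate zone, phenology, ...)
#' reports the squared Pearson product-moment correlation between observed
#' total NPP and Ecosystem Fit, the group size and the group centroid.
#' Groups smaller than `min_n` are skipped with a note; a group with zero
#' variance in either variable gets `NA` r-squared and a flag.
#'
#' @param results Data.frame holding `tnpp_obs` and `efit` columns (or the
#'   names given in `x`/`y`) plus the grouping column.
#' @param group_by Name of the grouping column.
#' @param x,y Column names of the correlated pair.
#' @param min_n Minimum group size reported (default 3).
#' @return Data.frame: group, n, r2, mean_x, mean_y, flag.
#' @export
groupwise_r2 <- function(results, group_by, x = "tnpp_obs", y = "efit",
                         min_n = 3) {
  for (col in c(group_by, x, y)) {
    if (!col %in% names(results)) {
      stop("groupwise_r2: column not found: ", col)
    }
  }
  keep <- !is.na(results[[x]]) & !is.na(results[[y]]) &
    !is.na(results[[group_by]])
  results <- results[keep, , drop = FALSE]
  groups <- unique(results[[group_by]])
  rows <- lapply(groups, function(g) {
    sub <- results[results[[group_by]] == g, , drop = FALSE]
    if (nrow(sub) < min_n) {
      return(data.frame(group = g, n = nrow(sub), r2 = NA_real_,
                        mean_x = NA_real_, mean_y = NA_real_,
                        flag = "below_min_n", stringsAsFactors = FALSE))
    }
    xv <- sub[[x]]; yv <- sub[[y]]
    flag <- ""
    r2 <- NA_real_
    if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
      flag <- "zero_variance"
    } else {
      r2 <- stats::cor(xv, yv)^2
    }
    data.frame(group = g, n = nrow(sub), r2 = r2, mean_x = mean(xv),
               mean_y = mean(yv), flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_x"] <- paste0("mean_", x)
  names(out)[names(out) == "mean_y"] <- paste0("mean_", y)
  rownames(out) <- NULL
  out
}
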