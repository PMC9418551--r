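test_that("dissimilarity matrix basics: Euclidean, symmetric, zero diag", {
  f <- data.frame(a = c(0, 3), b = c(0, 4))
  d <- as.matrix(dissimilarity_matrix(f, standardize = FALSE))
  expect_equal(d[1, 2], 5)  # 3-4-5 triangle
  expect_equal(d[2, 1], 5)
  expect_equal(diag(d), c("1" = 0, "2" = 0))

  set.seed(3)
  f2 <- matrix(rnorm(50 * 3), 50)
  d2 <- as.matrix(dissimilarity_matrix(f2))
  expect_equal(d2, t(d2))
  expect_true(all(diag(d2) == 0))
})

test_that("dissimilarity handles missing rows and zero-variance features", {
  f <- data.frame(site_id = c("a", "b", "c"),
                  x = c(1, NA, 3), y = c(2, 2, 2), z = c(5, 1, 9))
  expect_warning(
    expect_warning(d <- dissimilarity_matrix(f), "missing"),
    "zero-variance"
  )
  expect_equal(attr(d, "excluded_sites"), "b")
  expect_equal(attr(d, "Size"), 2L)
})

test_that("PAM separates well-separated clouds and is order invariant", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(20, 0, 0.2), ncol = 2),
               matrix(rnorm(20, 10, 0.2), ncol = 2))
  rownames(pts) <- sprintf("p%02d", 1:20)
  d <- dissimilarity_matrix(pts, standardize = FALSE)
  m <- pam_cluster(d, 2)
  truth <- rep(1:2, each = 10)
  # exact separation up to label permutation
  expect_equal(length(unique(m$assignment[1:10])), 1L)
  expect_equal(length(unique(m$assignment[11:20])), 1L)
  expect_false(m$assignment[1] == m$assignment[11])

  # shuffle row order: same partition up to cluster relabeling
  perm <- sample(20)
  m2 <- pam_cluster(dissimilarity_matrix(pts[perm, ], standardize = FALSE), 2)
  a1 <- m$assignment[rownames(pts)[perm]]
  a2 <- m2$assignment[rownames(pts)[perm]]
  expect_equal(length(unique(paste(a1, a2))), 2L)
})

test_that("PAM equals exhaustive medoid search on small instances", {
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    pts <- matrix(rnorm(n * 2), n)
    dm <- as.matrix(dist(pts))
    m <- pam_cluster(dm, k)
    expect_equal(m$cost, brute_force_pam_cost(dm, k), tolerance = 1e-12)
  }
})

test_that("heuristic BUILD+SWAP path is valid and near-exact", {
  set.seed(41)
  pts <- rbind(matrix(rnorm(30, 0, 0.5), ncol = 2),
               matrix(rnorm(30, 20, 0.5), ncol = 2),
               matrix(rnorm(30, c(0, 40), 0.5), ncol = 2))
  d <- dist(pts)
  # force the heuristic even though the instance is tiny enough for exact
  h <- pam_cluster(d, 3, exact_limit = 0)
  e <- pam_cluster(d, 3)
  # on well-separated clouds the heuristic reaches the exact optimum
  expect_equal(h$cost, e$cost, tolerance = 1e-12)
  expect_equal(sort(h$medoid_ids), sort(e$medoid_ids))
  # heuristic never beats exact, and always returns a full partition
  set.seed(42)
  for (rep in 1:10) {
    dm <- as.matrix(dist(matrix(rnorm(20), 10)))
    hh <- pam_cluster(dm, 3, exact_limit = 0)
    ee <- pam_cluster(dm, 3)
    expect_gte(hh$cost + 1e-12, ee$cost)
    expect_equal(length(hh$assignment), 10L)
  }
})

test_that("PAM structural invariants hold", {
  set.seed(9)
  pts <- matrix(rnorm(30), 15)
  rownames(pts) <- letters[1:15]
  m <- pam_cluster(dist(pts), 3)
  # every site assigned exactly once; medoids belong to their own cluster
  expect_equal(sort(names(m$assignment)), sort(letters[1:15]))
  med_idx <- match(m$medoid_ids, names(m$assignment))
  expect_equal(unname(m$assignment[med_idx]), 1:3)
  expect_true(m$avg_silhouette >= -1 && m$avg_silhouette <= 1)
  # k = n - 1: near-singletons; cost is the one non-medoid's gap
  m2 <- pam_cluster(dist(pts), 14)
  dm <- as.matrix(dist(pts))
  nonmed <- setdiff(letters[1:15], m2$medoid_ids)
  expect_equal(m2$cost, min(dm[nonmed, m2$medoid_ids]))
  expect_error(pam_cluster(dist(pts), 15), "k < n")
})

test_that("silhouette matches the textbook definition on a worked case", {
  # 4 points, 2 tight pairs far apart: silhouettes approach 1
  pts <- rbind(c(0, 0), c(0, 0.1), c(100, 0), c(100, 0.1))
  d <- dist(pts)
  s <- silhouette_widths(d, c(1, 1, 2, 2))
  expect_true(all(s > 0.99))
  # independent direct computation for point 1
  dm <- as.matrix(d)
  a1 <- dm[1, 2]
  b1 <- mean(dm[1, 3:4])
  expect_equal(s[1], (b1 - a1) / max(a1, b1))
  # singleton cluster contributes 0
  s2 <- silhouette_widths(d, c(1, 2, 3, 3))
  expect_equal(s2[1], 0)
})

test_that("select_k recovers the generating component count", {
  set.seed(23)
  for (k_true in 2:4) {
    centers <- seq(0, by = 50, length.out = k_true)
    pts <- do.call(rbind, lapply(centers, function(cc) {
      matrix(rnorm(16, cc, 1), ncol = 2)
    }))
    d <- dissimilarity_matrix(pts, standardize = FALSE)
    m <- select_k(d, 2:6)
    expect_equal(m$k, k_true)
    summ <- attr(m, "k_summary")
    expect_equal(summ$k, 2:6)
    expect_equal(max(summ$avg_silhouette), m$avg_silhouette)
  }
  # structureless single cloud: no k shines
  blob <- matrix(rnorm(60), ncol = 2)
  mb <- select_k(dissimilarity_matrix(blob, standardize = FALSE), 2:5)
  expect_lt(mb$avg_silhouette, 0.5)
})

test_that("groupwise_r2 reports per-group fits, sizes and centroids", {
  df <- data.frame(
    tnpp_obs = c(1, 2, 3, 4, 5, 5, 5, 10, 20),
    efit = c(2, 4, 6, 8, 3, 3, 3, 1, 2),
    zone = c(rep("lin", 4), rep("flat", 3), rep("tiny", 2))
  )
  out <- groupwise_r2(df, "zone")
  lin <- out[out$group == "lin", ]
  expect_equal(lin$r2, 1)                # exact linearity
  expect_equal(lin$n, 4)
  expect_equal(lin$mean_tnpp_obs, 2.5)
  expect_equal(lin$mean_efit, 5)
  flat <- out[out$group == "flat", ]
  expect_true(is.na(flat$r2))
  expect_equal(flat$flag, "zero_variance")
  tiny <- out[out$group == "tiny", ]
  expect_equal(tiny$flag, "below_min_n")
})

test_that("groupwise_r2 approaches the population r-squared", {
  set.seed(31)
  n <- 500
  rho <- 0.8
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  df <- data.frame(tnpp_obs = x, efit = y, zone = "z")
  out <- groupwise_r2(df, "zone")
  # r^2 ~ 0.64; sampling SE of r at n=500 is ~0.016, allow 3 SE on r^2 scale
  expect_lt(abs(out$r2 - 0.64), 3 * 2 * 0.8 * (1 - 0.64) / sqrt(n - 1))
})
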