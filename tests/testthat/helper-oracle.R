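# Independent straight-line transcription of the published model chain,
# kept free of any package function so it can serve as an oracle for
# evaluate_site(). Inputs: 12 monthly temps/srad, atmospheric CO2 (ppm),
# optional observed tNpp.
oracle_chain <- function(temp, srad, ca, obs = NA) {
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  warm <- !is.na(temp) & temp >= 0
  g_days <- sum(days[warm])
  if (g_days == 0) {
    return(list(g_days = 0, tnpp_tmax = 0, efit = NA_real_))
  }
  g_temp <- mean(temp[warm])
  g_srad <- mean(srad[warm], na.rm = TRUE)
  gamma <- exp(19.02 - 37.83 / (0.008314 * (g_temp + 273.15)))
  ci <- ca * 0.7
  wi <- ci / (4.5 * ci + 10.5 * gamma)
  a <- (1 - gamma / ci) * wi
  ec <- a * 0.45 * 0.9
  tn <- g_srad * g_days * 0.45 * 0.9 * ec / 1000 / 18.2 * 10
  if (a <= 0) tn <- 0
  list(g_days = g_days, g_temp = g_temp, g_srad = g_srad, gamma = gamma,
       ci = ci, wi = wi, a = a, ec = ec, tnpp_tmax = tn,
       efit = if (!is.na(obs) && tn > 0) 100 * obs / tn else NA_real_)
}

# Tiny CSV writers for fixture tables built in code.
write_site_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

make_climate_df <- function(ids, temps, srads) {
  rows <- lapply(seq_along(ids), function(i) {
    v <- as.list(c(temps[[i]], srads[[i]]))
    names(v) <- c(sprintf("temp_%02d", 1:12), sprintf("srad_%02d", 1:12))
    data.frame(site_id = ids[i], v, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Exhaustive k-medoid search: minimum cost over all C(n, k) medoid sets.
brute_force_pam_cost <- function(dm, k) {
  n <- nrow(dm)
  combos <- utils::combn(n, k)
  min(apply(combos, 2, function(med) {
    sum(apply(dm[, med, drop = FALSE], 1, min))
  }))
}
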