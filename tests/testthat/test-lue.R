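# Frozen expected values were computed with an independent straight-line
# evaluation of the closed forms before the implementation was written.
test_that("gamma_star matches the closed form and behaves physically", {
  expect_equal(gamma_star(25), exp(19.02 - 37.83 / (0.008314 * 298.15)))
  expect_equal(gamma_star(25), 42.892662711117623, tolerance = 1e-12)
  # standard C3 literature anchor (~42.75 at 25 degC): within 1%
  expect_lt(abs(gamma_star(25) - 42.75) / 42.75, 0.01)
  expect_lt(gamma_star(10), gamma_star(25))
  # approaches exp(-Inf) = 0 near absolute zero
  expect_lt(gamma_star(-273.14), 1e-300)
  expect_error(gamma_star(Inf), "finite")
  expect_error(gamma_star(-300), "absolute zero")
})

test_that("intercellular CO2 is a fixed fraction of atmospheric", {
  expect_equal(intercellular_co2(400), 280)
  expect_equal(intercellular_co2(400, lue_params(ci_ratio = 1)), 400)
  expect_error(intercellular_co2(0), "> 0")
})

test_that("W_i and A match frozen values and algebraic limits", {
  g25 <- gamma_star(25)
  expect_equal(rubisco_wi(280, g25), 0.16370698485025523, tolerance = 1e-12)
  expect_equal(rubisco_wi(280, 0), 1 / 4.5)
  expect_equal(net_uptake(280, g25), 0.13862902597655508, tolerance = 1e-12)
  # compensation point: uptake exactly zero when c_i = gamma_star
  expect_equal(net_uptake(g25, g25), 0)
  # below the compensation point A goes negative, returned as-is
  expect_lt(net_uptake(g25 / 2, g25), 0)
})

test_that("conversion efficiency and its bound", {
  a <- net_uptake(280, gamma_star(25))
  expect_equal(conversion_efficiency(a), 0.05614475552050481,
               tolerance = 1e-12)
  expect_equal(conversion_efficiency(0), 0)
  expect_equal(conversion_efficiency(a, lue_params(beta = 1, alpha_leaf = 1)),
               a)
})

test_that("tnpp_tmax implements the canonical unit chain", {
  gs <- derive_growing_season(monthly_climate(rep(25, 12), rep(16000, 12)))
  ec <- conversion_efficiency(net_uptake(280, gamma_star(25)))
  tn <- tnpp_tmax(gs, ec)
  expect_equal(tn, 16000 * 365 * 0.45 * 0.9 * ec / 1000 / 18.2 * 10)
  expect_equal(tn, 72.963503163240645, tolerance = 1e-12)
  # empty season gives exactly zero
  gs0 <- derive_growing_season(monthly_climate(rep(-5, 12), rep(1, 12)))
  expect_equal(tnpp_tmax(gs0, ec), 0)
  # linear homogeneity in radiation
  gs2 <- derive_growing_season(monthly_climate(rep(25, 12), rep(32000, 12)))
  expect_equal(tnpp_tmax(gs2, ec), 2 * tn)
  # the literal published product, exposed for comparison only
  expect_equal(tnpp_tmax(gs, ec, formula = "equation"),
               16000 * ec * 0.9 * 18.2)
})

test_that("ecosystem_fit is the percent ratio with over-100 flagged", {
  expect_equal(ecosystem_fit(72.9635, 72.9635), 100)
  expect_equal(ecosystem_fit(22, 72.963503163240645), 30.152061025331502,
               tolerance = 1e-12)
  expect_equal(ecosystem_fit(22, 88, ratio = TRUE), 0.25)
  expect_warning(ecosystem_fit(110, 100), "exceeds")
  expect_error(ecosystem_fit(10, 0), "undefined")
})

test_that("evaluate_site composes the full chain with intermediates", {
  mc <- monthly_climate(rep(25, 12), rep(16000, 12))
  co2 <- co2_table(c(2000, 2001), c(400, 410))
  site <- list(site_id = "u", year = 2000, tnpp_obs = 22)
  r <- evaluate_site(site, mc, co2)
  expect_equal(r$c_a, 400)
  expect_equal(r$c_i, 280)
  expect_equal(r$gamma_star, gamma_star(25))
  expect_equal(r$tnpp_tmax, 72.963503163240645, tolerance = 1e-12)
  expect_equal(r$efit, 30.152061025331502, tolerance = 1e-12)
  expect_equal(r$flags, "")
  # determinism: identical inputs, identical outputs
  expect_identical(evaluate_site(site, mc, co2), r)
})

test_that("evaluate_site degenerate paths flag instead of failing", {
  co2 <- co2_table(2000, 400)
  frozen <- monthly_climate(rep(-10, 12), rep(1000, 12))
  r <- evaluate_site(list(site_id = "f", year = 2000, tnpp_obs = 5),
                     frozen, co2)
  expect_equal(r$tnpp_tmax, 0)
  expect_true(is.na(r$efit))
  expect_match(r$flags, "empty_season")
  expect_match(r$flags, "efit_undefined")

  # unresolvable CO2 year
  r2 <- evaluate_site(list(site_id = "y", year = 1700, tnpp_obs = 5),
                      monthly_climate(rep(20, 12), rep(1000, 12)), co2)
  expect_match(r2$flags, "co2_unresolved")
  expect_true(is.na(r2$tnpp_tmax))

  # ... but the fallback rescues it
  r3 <- evaluate_site(list(site_id = "y", year = 1700, tnpp_obs = 5),
                      monthly_climate(rep(20, 12), rep(1000, 12)), co2,
                      fallback_ppm = 400)
  expect_equal(r3$c_a, 400)
  expect_false(grepl("co2_unresolved", r3$flags))
})

test_that("evaluate_sites never aborts on one bad site", {
  co2 <- co2_table(2000, 400)
  sites <- data.frame(site_id = c("good", "noclimate"),
                      lon = 0, lat = 0, year = 2000,
                      tnpp_obs = c(10, 10))
  climates <- list(good = monthly_climate(rep(20, 12), rep(15000, 12)))
  res <- evaluate_sites(sites, climates, co2 = co2)
  expect_equal(nrow(res), 2)
  expect_equal(res$flags[1], "")
  expect_match(res$flags[2], "^error:")
  expect_gt(res$tnpp_tmax[1], 0)
})

test_that("monotonicity and bounds hold over randomized probes", {
  set.seed(11)
  p <- lue_params()
  for (i in 1:200) {
    t1 <- runif(1, -5, 35)
    dt <- runif(1, 0.1, 10)
    ca <- runif(1, 200, 900)
    dca <- runif(1, 5, 100)
    # gamma* strictly increasing in temperature
    expect_lt(gamma_star(t1), gamma_star(t1 + dt))
    ec_fun <- function(tt, cc) {
      conversion_efficiency(net_uptake(intercellular_co2(cc), gamma_star(tt)))
    }
    # eps_c decreasing in T (photorespiration), increasing in c_a
    expect_gt(ec_fun(t1, ca), ec_fun(t1 + dt, ca))
    expect_lt(ec_fun(t1, ca), ec_fun(t1, ca + dca))
    # global bound eps_c < beta * alpha / 4.5
    expect_lt(ec_fun(t1, ca), p$beta * p$alpha_leaf / 4.5)
    # W_i below its algebraic ceiling
    expect_lt(rubisco_wi(intercellular_co2(ca), gamma_star(t1)), 1 / 4.5)
  }
})

test_that("evaluate_site matches the independent script transcription", {
  set.seed(101)
  co2 <- co2_table(2000, 400)
  for (i in 1:100) {
    temps <- runif(12, -15, 32)
    srads <- runif(12, 2000, 22000)
    obs <- runif(1, 1, 30)
    mc <- monthly_climate(temps, srads)
    got <- evaluate_site(list(site_id = "x", year = 2000, tnpp_obs = obs),
                         mc, co2)
    want <- oracle_chain(temps, srads, 400, obs)
    expect_equal(got$g_days, want$g_days)
    if (want$g_days > 0) {
      expect_equal(got$tnpp_tmax, want$tnpp_tmax, tolerance = 1e-10)
      if (want$tnpp_tmax > 0) {
        expect_equal(got$efit, want$efit, tolerance = 1e-10)
      }
    } else {
      expect_equal(got$tnpp_tmax, 0)
    }
  }
})
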