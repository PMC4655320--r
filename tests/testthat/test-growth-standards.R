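test_that("Hadlock EFW equals an independent evaluation of the registered polynomial", {
  # oracle: hand evaluation of the published log10 regression
  oracle3 <- function(hc, ac, fl)
    10^(1.326 - 0.00326 * ac * fl + 0.0107 * hc + 0.0438 * ac + 0.158 * fl)
  oracle4 <- function(bpd, hc, ac, fl)
    10^(1.3596 - 0.00386 * ac * fl + 0.0064 * hc + 0.00061 * bpd * ac +
          0.0424 * ac + 0.174 * fl)
  expect_equal(hadlock_efw(30, 26, 5.5), oracle3(30, 26, 5.5), tolerance = 1e-12)
  expect_equal(hadlock_efw(c(30, 32), c(26, 30), c(5.5, 6.2)),
               oracle3(c(30, 32), c(26, 30), c(5.5, 6.2)), tolerance = 1e-12)
  expect_equal(hadlock_efw(30, 26, 5.5, bpd_cm = 8, variant = "bpdhcacfl"),
               oracle4(8, 30, 26, 5.5), tolerance = 1e-12)
})

test_that("EFW is strictly increasing in AC and invariant to unit round-trips", {
  expect_lt(hadlock_efw(30, 26, 5.5), hadlock_efw(30, 27, 5.5))
  # mm -> cm -> mm round trip leaves the result unchanged
  hc <- 30.17; ac <- 26.62; fl <- 5.53
  expect_equal(hadlock_efw(hc, ac, fl),
               hadlock_efw((hc * 10) / 10, (ac * 10) / 10, (fl * 10) / 10),
               tolerance = 1e-12)
})

test_that("Hadlock EFW rejects missing and nonpositive inputs", {
  expect_error(hadlock_efw(NA, 26, 5.5), class = "gs_missing_input")
  expect_error(hadlock_efw(30, 26, 5.5, variant = "bpdhcacfl"),
               class = "gs_missing_input")
  expect_error(hadlock_efw(30, -1, 5.5), class = "gs_domain_error")
  expect_error(hadlock_efw(30, 26, 5.5, variant = "nope"))
})

test_that("EFW percentile maps location and location + 1 SD correctly", {
  std <- toy_efw_standard()
  ga <- c(24, 30, 36.5)
  expect_equal(efw_percentile(100 * ga, ga, std), rep(50, 3),
               tolerance = 1e-12)
  expect_equal(efw_percentile(100 * ga * 1.1, ga, std),
               rep(100 * pnorm(1), 3), tolerance = 1e-9)
})

test_that("EFW percentile matches a direct normal-CDF oracle and is strictly increasing", {
  std <- toy_efw_standard()
  set.seed(1)
  ga <- runif(50, 14, 42)
  efw <- 100 * ga * (1 + 0.1 * rnorm(50))
  oracle <- 100 * pnorm((efw - 100 * ga) / (10 * ga))
  expect_equal(efw_percentile(efw, ga, std), oracle, tolerance = 1e-12)
  for (g in c(22, 33, 40)) {
    v <- efw_percentile(100 * g * c(0.8, 0.9, 1, 1.1, 1.2), rep(g, 5), std)
    expect_true(all(diff(v) > 0))
  }
})

test_that("EFW percentile refuses gestational ages outside the standard domain", {
  err <- expect_error(efw_percentile(1000, 50, toy_efw_standard()),
                      class = "gs_range_error")
  expect_match(conditionMessage(err), "12")
  expect_error(efw_percentile(1000, 30, toy_bw_standard()),
               class = "gs_config_error")
})

test_that("birthweight percentile reproduces the table and separates sexes", {
  std <- toy_bw_standard()
  # tabulated median -> 50th percentile
  expect_equal(birthweight_percentile(200 * 18 + 100, 38, "M", std), 50,
               tolerance = 1e-9)
  expect_equal(birthweight_percentile(200 * 18, 38, "F", std), 50,
               tolerance = 1e-9)
  # same weight, different sexes -> different percentiles
  expect_false(birthweight_percentile(3000, 38, "M", std) ==
                 birthweight_percentile(3000, 38, "F", std))
  # linear table: interpolated location at a half-week equals the average
  # of the neighbouring rows (hand oracle)
  mid <- (200 * 18 + 200 * 19) / 2 + 100
  expect_equal(birthweight_percentile(mid, 38.5, "M", std), 50,
               tolerance = 1e-9)
  expect_error(birthweight_percentile(3000, 22, "M", std),
               class = "gs_range_error")
})

test_that("customised percentile is deterministic and degenerates to the population percentile", {
  # zero-adjustment coefficient set anchored at the toy standard's term weight
  std <- toy_efw_standard()
  coefs <- list(term_ga_weeks = 40, base_term_weight_g = 4000,
                reference_height_cm = 163, reference_weight_kg = 65,
                height_g_per_cm = 0, weight_g_per_kg = 0, smoker_g = 0,
                ethnicity_g = list(white = 0), cv = 0.1)
  p1 <- customised_percentile(3000, 36, 170, 80, coefs = coefs, standard = std)
  p2 <- customised_percentile(3000, 36, 170, 80, coefs = coefs, standard = std)
  expect_identical(p1, p2)
  expect_equal(p1, efw_percentile(3000, 36, std), tolerance = 1e-12)
  # positive height coefficient: taller mother -> higher expected weight ->
  # lower percentile for the same EFW
  coefs$height_g_per_cm <- 8
  tall <- customised_percentile(3000, 36, 178, 65, coefs = coefs, standard = std)
  short <- customised_percentile(3000, 36, 158, 65, coefs = coefs, standard = std)
  expect_lt(tall, short)
  expect_error(customised_percentile(3000, 36, 170, 80, ethnicity = "unknown",
                                     coefs = coefs, standard = std),
               class = "gs_config_error")
  expect_error(fg_customisation("/nonexistent/coefs.json"),
               class = "gs_config_error")
})

test_that("shipped standards registry loads and is self-consistent", {
  std <- fg_standard("hadlock1991_efw_ga")
  expect_s3_class(std, "growth_standard")
  # median input -> 50th percentile across the whole GA domain
  ga <- seq(std$ga_range[1], std$ga_range[2], by = 0.25)
  expect_true(all(abs(efw_percentile(std$location(ga), ga, std) - 50) < 1e-9))
  bw <- fg_standard("birthweight_uk_synthetic")
  expect_identical(bw$kind, "birthweight_for_ga_sex")
  expect_error(fg_standard("no_such_standard"), class = "gs_config_error")
})

test_that("Z-score model recovers known generating curves", {
  set.seed(7)
  n <- 5000
  ga <- runif(n, 20, 40)
  m <- function(g) 2 + 0.9 * g - 0.004 * g^2
  s <- function(g) 0.5 + 0.02 * g
  y <- m(ga) + rnorm(n, 0, s(ga))
  fit <- fit_zscore_model(ga, y, degree = 2)
  # held-out points: recovered Z within +/- 0.1 of the true Z
  ga_new <- c(22, 26, 30, 34, 37)
  y_new <- m(ga_new) + c(-1.5, -0.3, 0, 0.8, 2) * s(ga_new)
  z_true <- (y_new - m(ga_new)) / s(ga_new)
  expect_true(all(abs(zscore(fit, ga_new, y_new) - z_true) < 0.1))
  # mean-curve recovery within 2% over the central 90% of the GA range
  grid <- seq(quantile(ga, 0.05), quantile(ga, 0.95), length.out = 50)
  rel_err <- abs(growthscreen:::zmodel_mean(fit, grid) - m(grid)) / m(grid)
  expect_lt(max(rel_err), 0.02)
  # self-sample calibration
  z_self <- zscore(fit, ga, y)
  expect_lt(abs(mean(z_self)), 0.05)
  expect_true(sd(z_self) > 0.9 && sd(z_self) < 1.1)
})

test_that("Z-score model is exact on its own fitted curves", {
  set.seed(8)
  ga <- runif(500, 25, 39)
  y <- 10 + ga + rnorm(500)
  fit <- fit_zscore_model(ga, y, degree = 1)
  g <- c(26, 30, 38)
  on_curve <- growthscreen:::zmodel_mean(fit, g)
  expect_equal(zscore(fit, g, on_curve), rep(0, 3), tolerance = 1e-9)
  plus2 <- on_curve + 2 * growthscreen:::zmodel_sd(fit, g)
  expect_equal(zscore(fit, g, plus2), rep(2, 3), tolerance = 1e-9)
})

test_that("Z-score model rejects degenerate designs", {
  expect_error(fit_zscore_model(rep(30, 200), rnorm(200)),
               class = "gs_fit_error")
  expect_error(fit_zscore_model(runif(50, 20, 40), rnorm(50)),
               class = "gs_fit_error")
})

test_that("growth velocity is the difference of Z-scores", {
  expect_identical(ac_growth_velocity(0.5, 0.5), 0)
  expect_identical(ac_growth_velocity(1.0, -0.5), -1.5)
  expect_error(ac_growth_velocity(NA, 1), class = "gs_missing_input")
  expect_error(ac_growth_velocity(0, Inf), class = "gs_missing_input")
})
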