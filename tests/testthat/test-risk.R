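test_that("relative risk matches hand calculation with the Katz interval", {
  tab <- matrix(c(20, 80, 10, 90), 2, 2, byrow = TRUE)
  r <- relative_risk(tab)
  expect_identical(r$rr, 2)
  se <- sqrt(1 / 20 - 1 / 100 + 1 / 10 - 1 / 100)
  expect_equal(r$lower, 2 * exp(-qnorm(0.975) * se), tolerance = 1e-12)
  expect_equal(r$upper, 2 * exp(qnorm(0.975) * se), tolerance = 1e-12)
  expect_false(r$continuity)
})

test_that("equal risks give RR 1 and Fisher p 1 on a balanced symmetric table", {
  r <- relative_risk(matrix(c(15, 85, 15, 85), 2, 2, byrow = TRUE))
  expect_identical(r$rr, 1)
  expect_identical(r$p_fisher, 1)
})

test_that("Fisher exact p equals exhaustive hypergeometric enumeration", {
  set.seed(41)
  for (i in 1:30) {
    tab <- matrix(rpois(4, lambda = sample(2:12, 1)) + 1, 2, 2)
    expect_equal(relative_risk(tab)$p_fisher, fisher_enum_p(tab),
                 tolerance = 1e-9)
    # transposition invariance
    expect_equal(relative_risk(tab)$p_fisher, fisher.test(t(tab))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("relative risk is equivariant under exposure swap and handles zero cells", {
  tab <- matrix(c(12, 88, 30, 70), 2, 2, byrow = TRUE)
  r <- relative_risk(tab)
  r_swap <- relative_risk(tab[2:1, ])
  expect_equal(r_swap$rr, 1 / r$rr, tolerance = 1e-12)
  # zero events in the reference arm: infinite RR, continuity-corrected CI
  rz <- relative_risk(matrix(c(5, 45, 0, 50), 2, 2, byrow = TRUE))
  expect_true(rz$infinite)
  expect_true(rz$continuity)
  expect_true(is.finite(rz$lower))
  expect_error(relative_risk(matrix(c(0, 50, 0, 50), 2, 2, byrow = TRUE)),
               class = "gs_undefined_metric")
  expect_error(relative_risk(matrix(c(0, 0, 3, 50), 2, 2, byrow = TRUE)),
               class = "gs_undefined_metric")
})

test_that("homogeneous strata give a large interaction p, heterogeneous a small one", {
  same <- matrix(c(100, 900, 50, 950), 2, 2, byrow = TRUE)
  r_same <- mh_interaction(same, same)
  expect_gt(r_same$p, 0.9)
  # RR 1 vs RR 4 at n = 2000 per stratum
  s1 <- matrix(c(50, 950, 50, 950), 2, 2, byrow = TRUE)
  s2 <- matrix(c(200, 800, 50, 950), 2, 2, byrow = TRUE)
  r <- mh_interaction(s1, s2)
  expect_lt(r$p, 0.01)
  # cross-method agreement with the logistic interaction within 2-fold
  expect_true(r$p / r$p_logistic < 2 && r$p_logistic / r$p < 2 ||
                (r$p < 1e-6 && r$p_logistic < 1e-6))
  expect_error(mh_interaction(s1, matrix(c(0, 0, 5, 50), 2, 2, byrow = TRUE)),
               class = "gs_undefined_metric")
})

test_that("interaction p agrees with a permutation oracle on small strata", {
  # permutation scheme: shuffle stratum membership over subjects, keeping
  # each subject's (exposure, outcome) pair, and recompute the absolute
  # log-RR difference with 0.5 continuity correction
  perm_p <- function(t1, t2, B = 10000, seed = 17) {
    expand <- function(tab) cbind(
      exposed = rep(c(1, 1, 0, 0), times = as.vector(t(tab))),
      outcome = rep(c(1, 0, 1, 0), times = as.vector(t(tab))))
    dat <- rbind(expand(t1), expand(t2))
    n1 <- sum(t1)
    lrr <- function(tab) {
      tab <- tab + 0.5
      log((tab[1, 1] / sum(tab[1, ])) / (tab[2, 1] / sum(tab[2, ])))
    }
    tab_of <- function(rows) {
      matrix(c(sum(rows[, 1] & rows[, 2]), sum(rows[, 1] & !rows[, 2]),
               sum(!rows[, 1] & rows[, 2]), sum(!rows[, 1] & !rows[, 2])),
             2, 2, byrow = TRUE)
    }
    obs <- abs(lrr(t1) - lrr(t2))
    set.seed(seed)
    stats <- replicate(B, {
      idx <- sample(nrow(dat), n1)
      abs(lrr(tab_of(dat[idx, , drop = FALSE])) -
            lrr(tab_of(dat[-idx, , drop = FALSE])))
    })
    mean(stats >= obs - 1e-12)
  }
  cases <- list(
    list(matrix(c(8, 22, 5, 25), 2, 2, byrow = TRUE),
         matrix(c(12, 18, 4, 26), 2, 2, byrow = TRUE)),
    list(matrix(c(10, 20, 10, 20), 2, 2, byrow = TRUE),
         matrix(c(18, 12, 6, 24), 2, 2, byrow = TRUE))
  )
  for (cs in cases) {
    p_mh <- mh_interaction(cs[[1]], cs[[2]])$p
    p_perm <- perm_p(cs[[1]], cs[[2]])
    expect_lt(abs(p_mh - p_perm), 0.05)
  }
})

test_that("stratified report has the expected layout and null cohorts give null RRs", {
  cls <- classify_cohort(small_cohort(n = 300, seed = 51))
  rep <- table4_report(cls)
  expect_identical(sort(unique(rep$exposure)),
                   sort(c("efw_lt10_population", "efw_lt10_customised",
                          "efw_lt10_normal_acgv", "efw_lt10_lowest_acgv")))
  expect_identical(sort(unique(rep$outcome)),
                   sort(c("neonatal_morbidity", "metabolic_acidosis",
                          "low_apgar5", "nnu_admission_term",
                          "sga_plus_morbidity", "severe_adverse",
                          "sga_plus_severe")))
  expect_identical(nrow(rep), 28L)
  expect_true(!is.null(attr(rep, "tables")))
  expect_error(table4_report(data.frame(x = 1)), class = "gs_missing_input")

  # outcome independent of all flags: RRs hover around 1
  set.seed(52)
  n <- 3977
  null_cls <- data.frame(
    universal_status = sample(c("positive", "negative"), n, TRUE, c(0.14, 0.86)),
    customised_status = sample(c("positive", "negative"), n, TRUE, c(0.14, 0.86)),
    acgv = rnorm(n),
    acgv_bottom_decile = runif(n) < 0.1,
    neonatal_morbidity = runif(n) < 0.3,
    metabolic_acidosis = runif(n) < 0.25,
    low_apgar5 = runif(n) < 0.25,
    nnu_admission_term = runif(n) < 0.25,
    sga_plus_morbidity = runif(n) < 0.25,
    severe_adverse = runif(n) < 0.25,
    sga_plus_severe = runif(n) < 0.25
  )
  rr <- table4_report(null_cls)$rr
  expect_true(all(rr > 0.7 & rr < 1.4))
})

test_that("velocity stratification separates risk in the synthetic cohort design", {
  # the generator's latent FGR class should make screen-positive pregnancies
  # with decelerating abdominal growth the high-risk subgroup
  ok <- 0
  n_seeds <- 100
  for (s in seq_len(n_seeds)) {
    cls <- classify_cohort(generate_cohort(cohort_params(seed = 1000 + s)))
    rep <- table4_report(cls)
    rr_low <- rep$rr[rep$exposure == "efw_lt10_lowest_acgv" &
                       rep$outcome == "neonatal_morbidity"]
    rr_norm <- rep$rr[rep$exposure == "efw_lt10_normal_acgv" &
                        rep$outcome == "neonatal_morbidity"]
    if (is.finite(rr_low) && is.finite(rr_norm) && rr_low > rr_norm)
      ok <- ok + 1
  }
  expect_gte(ok, 0.95 * n_seeds)
})
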