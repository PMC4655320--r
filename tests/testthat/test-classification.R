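test_that("selective policy is negative without a clinically indicated scan at 26 weeks or later", {
  # only research scans
  s <- make_scans(c(20, 28.2, 36.1), c("research20", "research28", "research36"))
  r <- classify_policy(s, ga_delivery = 40, policy = "selective")
  expect_identical(r$status, "negative")
  expect_true(is.na(r$efw_percentile))
  # clinical scan too early to be eligible
  s2 <- make_scans(25.5, "selective", ac = 200)
  expect_identical(classify_policy(s2, 40, "selective")$status, "negative")
})

test_that("screen-positive threshold is strict and the last scan governs", {
  s <- make_scans(34, "selective", hc = 310, ac = 290, fl = 64)
  pct <- classify_policy(s, 40, "selective")$efw_percentile
  # threshold exactly at the observed percentile -> negative (strict <)
  expect_identical(classify_policy(s, 40, "selective",
                                   threshold = pct)$status, "negative")
  expect_identical(classify_policy(s, 40, "selective",
                                   threshold = pct + 1e-9)$status, "positive")
  # two eligible scans, small then normal in GA order -> negative
  s3 <- rbind(make_scans(30, "selective", hc = 250, ac = 215, fl = 50),
              make_scans(36, "selective", hc = 330, ac = 325, fl = 70))
  r <- classify_policy(s3, 40, "selective")
  expect_identical(r$status, "negative")
  expect_equal(r$scan_ga_weeks, 36)
  # shuffled input gives the identical result (internal sort)
  expect_identical(classify_policy(s3[2:1, ], 40, "selective"), r)
  # scans after delivery are ignored
  s4 <- rbind(make_scans(30, "research28"), make_scans(36, "research36"))
  r4 <- classify_policy(s4, 31, "universal")
  expect_equal(r4$scan_ga_weeks, 30)
})

test_that("universal policy without an eligible research scan signals exclusion", {
  s <- make_scans(20, "research20")
  expect_error(classify_policy(s, 40, "universal"),
               class = "gs_exclusion_error")
})

test_that("gold standard thresholds are strict and nested", {
  gs <- gold_standard(c(9.9, 2.9, 10.0, 3.0, 50))
  expect_identical(gs$sga, c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_identical(gs$severe_sga, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(gs$sga[gs$severe_sga]))
})

test_that("composite morbidity follows the component definitions at their boundaries", {
  flags <- neonatal_morbidity(rbind(
    make_outcome(apgar5 = 6),                                   # 1 low Apgar
    make_outcome(cord_ph = 7.10, cord_base_deficit = 10.0),     # 2 boundary: not acidosis
    make_outcome(cord_ph = 7.09, cord_base_deficit = 10.1),     # 3 acidosis
    make_outcome(ga_delivery_weeks = 36, nnu_admission = TRUE,  # 4 preterm admission
                 nnu_admit_hours = 5, nnu_discharge_hours = 100),
    make_outcome(nnu_admission = TRUE, nnu_admit_hours = 47.9,  # 5 term admission
                 nnu_discharge_hours = 48),
    make_outcome(nnu_admission = TRUE, nnu_admit_hours = 5,     # 6 short stay
                 nnu_discharge_hours = 47.9),
    make_outcome()                                              # 7 healthy
  ))
  expect_identical(flags$neonatal_morbidity,
                   c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(flags$nnu_admission_term,
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("severe adverse composite requires term livebirth except for stillbirth", {
  flags <- neonatal_morbidity(rbind(
    make_outcome(mechanical_ventilation = TRUE, ga_delivery_weeks = 36),
    make_outcome(mechanical_ventilation = TRUE),
    make_outcome(cord_ph = 6.99, cord_base_deficit = 12.1),
    make_outcome(cord_ph = 7.0, cord_base_deficit = 12.1),   # boundary
    make_outcome(stillbirth = TRUE, ga_delivery_weeks = 35)
  ))
  expect_identical(flags$severe_adverse, c(FALSE, TRUE, TRUE, FALSE, TRUE))
})

test_that("contradictory admission fields raise a validation error and missing fields are logged", {
  expect_error(neonatal_morbidity(make_outcome(nnu_admission = TRUE,
                                               nnu_admit_hours = 5,
                                               nnu_discharge_hours = -2)),
               class = "gs_validation_error")
  flags <- neonatal_morbidity(rbind(make_outcome(apgar5 = NA),
                                    make_outcome(cord_ph = NA)))
  expect_identical(flags$neonatal_morbidity, c(FALSE, FALSE))
  expect_identical(unname(attr(flags, "missing_log")[c("apgar5", "cord_ph")]),
                   c(1L, 1L))
})

test_that("decile flags count correctly and never flag ties at the cut", {
  f <- decile_flags(0:99, "lowest")
  expect_identical(sum(f), 10L)
  expect_true(all(which(f) <= 10))
  f2 <- decile_flags(0:99, "highest")
  expect_identical(sum(f2), 10L)
  expect_true(all(which(f2) >= 91))
  expect_identical(sum(decile_flags(rep(1, 50), "lowest")), 0L)
  set.seed(5)
  f3 <- decile_flags(rnorm(1000), "lowest")
  expect_true(sum(f3) >= 80 && sum(f3) <= 120)
  # missing values flagged FALSE and logged
  f4 <- decile_flags(c(rnorm(50), NA, NA), "lowest")
  expect_identical(attr(f4, "n_missing"), 2L)
  expect_false(any(f4[51:52]))
  expect_error(decile_flags(rep(NA_real_, 20), "lowest"),
               class = "gs_missing_input")
})

test_that("cohort classification is invariant to row order and conserves margins", {
  co <- small_cohort(n = 300, seed = 21)
  cls <- classify_cohort(co)
  set.seed(1)
  sh_scans <- co$scans[sample(nrow(co$scans)), ]
  sh_out <- co$outcomes[sample(nrow(co$outcomes)), ]
  cls2 <- classify_cohort(sh_scans, sh_out, co$maternal)
  for (col in c("selective_status", "universal_status", "sga",
                "acgv_bottom_decile", "neonatal_morbidity"))
    expect_identical(cls[[col]], cls2[[col]])
  counts <- screening_counts(cls)
  expect_true(all(counts$yes[counts$row == "total"] +
                    counts$no[counts$row == "total"] == nrow(cls)))
  expect_true(all(tapply(counts$total[counts$row != "total"],
                         paste(counts$policy, counts$outcome)[counts$row != "total"],
                         sum) == nrow(cls)))
})

test_that("derived flags are nested as defined", {
  cls <- classify_cohort(small_cohort(n = 400, seed = 22))
  expect_true(all(cls$sga[cls$severe_sga]))
  expect_identical(cls$sga_plus_morbidity, cls$sga & cls$neonatal_morbidity)
  expect_identical(cls$sga_plus_severe, cls$sga & cls$severe_adverse)
  # a selective-negative subject never carries a selective percentile < 10
  neg <- cls$selective_status == "negative"
  expect_true(all(is.na(cls$selective_efw_percentile[neg]) |
                    cls$selective_efw_percentile[neg] >= 10))
})
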