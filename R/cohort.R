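#' Parameters for the synthetic screening cohort
#'
#' Defaults emulate the statistical structure of a nulliparous screening
#' cohort of ~4000 pregnancies: ~9% SGA prevalence, ~42% receiving a
#' clinically indicated third-trimester scan, a latent fetal-growth-restriction
#' (FGR) subgroup (~4.3%) with decelerating abdominal-circumference growth,
#' ~10% CV measurement error on estimated fetal weight, and composite neonatal
#' morbidity near 7% with a ~3.9-fold risk ratio for growth-restricted SGA.
#'
#' @param n_subjects cohort size.
#' @param sga_prevalence target marginal probability of birthweight < 10th
#'   percentile.
#' @param fgr_latent_prevalence probability of the latent FGR class.
#' @param selective_scan_rate fraction with a clinically indicated scan at
#'   26 weeks or later.
#' @param efw_measurement_cv coefficient of variation of measured EFW around
#'   the true fetal size.
#' @param morbidity_base_rate marginal probability of composite neonatal
#'   morbidity.
#' @param rr_morbidity_given_sga_lowvelocity risk of morbidity among
#'   growth-restricted SGA infants relative to non-FGR infants.
#' @param velocity_deficit mean AC Z-score change (20 weeks to term) in the
#'   FGR class; negative.
#' @param velocity_deficit_sd between-subject SD of that deficit.
#' @param late_growth_sd SD of true growth drift between the last scan and
#'   delivery (Z-score units).
#' @param efw_standard_offset systematic offset (Z units) of the in-utero EFW
#'   standard relative to the birthweight standard; positive values make EFW
#'   percentiles read lower than birth percentiles, as observed when an
#'   in-utero reference is paired with a national birthweight reference.
#' @param clinical_efw_shift systematic offset (Z units) of clinically
#'   measured EFW relative to research-protocol EFW (routine scans read
#'   larger), which lowers selective-screen sensitivity.
#' @param clinical_extra_cv additional EFW measurement CV on clinically
#'   indicated scans.
#' @param smallness_indication_coef weight of (negative) fetal size in the
#'   logistic model selecting women for clinically indicated scans
#'   (symphyseal-fundal-height proxy).
#' @param severe_adverse_rate marginal probability of the severe adverse
#'   perinatal composite.
#' @param seed integer seed; expanded into per-subject substreams so that
#'   enlarging the cohort never perturbs existing subjects.
#' @return a validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 3977,
                          sga_prevalence = 0.09,
                          fgr_latent_prevalence = 0.043,
                          selective_scan_rate = 0.42,
                          efw_measurement_cv = 0.10,
                          morbidity_base_rate = 0.069,
                          rr_morbidity_given_sga_lowvelocity = 3.9,
                          velocity_deficit = -1.2,
                          velocity_deficit_sd = 0.3,
                          late_growth_sd = 0.7,
                          efw_standard_offset = 0.3,
                          clinical_efw_shift = 0.6,
                          clinical_extra_cv = 0.06,
                          smallness_indication_coef = 0.35,
                          severe_adverse_rate = 0.0083,
                          seed = 1L) {
  p <- as.list(environment())
  rates <- c("sga_prevalence", "fgr_latent_prevalence", "selective_scan_rate",
             "efw_measurement_cv", "morbidity_base_rate", "severe_adverse_rate")
  for (r in rates)
    if (!(p[[r]] > 0 && p[[r]] < 1))
      stop_gs("parameter '%s' = %g must be in (0, 1)", r, p[[r]],
              class = "gs_param_error")
  if (n_subjects < 100)
    stop_gs("n_subjects = %d; need at least 100", n_subjects,
            class = "gs_param_error")
  if (rr_morbidity_given_sga_lowvelocity < 1)
    stop_gs("rr_morbidity_given_sga_lowvelocity must be >= 1",
            class = "gs_param_error")
  if (velocity_deficit > 0)
    stop_gs("velocity_deficit is a deficit and must be <= 0",
            class = "gs_param_error")
  structure(p, class = "cohort_params")
}

# Median biometry curves and per-measure fractional SDs for the generator.
biometry_reference <- function() {
  path <- system.file("extdata", "standards", "biometry_reference_synthetic.json",
                      package = "growthscreen")
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  funs <- lapply(spec$median_cm, function(v)
    stats::splinefun(spec$ga_knots, v, method = "monoH.FC"))
  list(median = funs, frac_sd = spec$fractional_sd_per_z)
}

# FGR deceleration ramp: deficit is absent at 20 weeks and fully expressed
# by 40 weeks.
fgr_ramp <- function(ga) pmax(0, (ga - 20) / 20)

# Baseline latent-size mean solving the marginal SGA prevalence under the
# FGR mixture (analytic, parameters only -- binomial sampling variation in
# the realised prevalence is preserved).
calibrate_mu0 <- function(p) {
  thr <- stats::qnorm(0.10)
  pf <- p$fgr_latent_prevalence
  rbar <- 0.98  # mean deceleration ramp at delivery
  s1 <- sqrt(1 + p$late_growth_sd^2)
  s2 <- sqrt(1 + p$late_growth_sd^2 + (p$velocity_deficit_sd * rbar)^2)
  f <- function(mu0)
    (1 - pf) * stats::pnorm(thr, mu0, s1) +
      pf * stats::pnorm(thr, mu0 + p$velocity_deficit * rbar, s2) -
      p$sga_prevalence
  stats::uniroot(f, c(-2, 2), tol = 1e-9)$root
}

# Invert the Hadlock HC/AC/FL equation for a common biometry scale factor:
# with all measures scaled by lambda from the GA medians, log10(EFW) is
# quadratic in lambda, so the factor hitting a target EFW is closed-form.
solve_biometry_lambda <- function(efw_target, hc_med, ac_med, fl_med, eq) {
  A <- eq$ac_fl * ac_med * fl_med
  B <- eq$hc * hc_med + eq$ac * ac_med + eq$fl * fl_med
  C <- eq$intercept - log10(efw_target)
  disc <- B^2 - 4 * A * C
  disc <- pmax(disc, 0)
  r1 <- (-B + sqrt(disc)) / (2 * A)
  r2 <- (-B - sqrt(disc)) / (2 * A)
  ifelse(abs(r1 - 1) <= abs(r2 - 1), r1, r2)
}

#' Generate a synthetic screening cohort
#'
#' Simulates per-pregnancy maternal characteristics, a latent fetal growth
#' percentile with a latent FGR class applying a progressive growth deficit,
#' research scans at ~20/28/36 weeks, clinically indicated scans selected by
#' a logistic indication model correlated with true fetal smallness, and
#' birth outcomes (birthweight from the registered birthweight standard,
#' composite neonatal morbidity from a logistic model on latent FGR and SGA
#' status, with component fields sampled conditional on the composite).
#' Biometry is emitted in mm; its Hadlock EFW is consistent with the latent
#' size by closed-form inversion of the Hadlock equation.
#'
#' @param params a [cohort_params()] object.
#' @return an object of class `fg_cohort`: list with data frames `maternal`,
#'   `scans`, `outcomes`, the latent `truth` ledger, and `params`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  p <- params
  n <- p$n_subjects
  bio <- biometry_reference()
  eq <- load_efw_equation("hcacfl")
  efw_std <- fg_standard("hadlock1991_efw_ga")
  bw_std <- fg_standard("birthweight_uk_synthetic")
  mu0 <- calibrate_mu0(p)

  # EFW measurement-noise budget. Multiplicative biometry errors propagate to
  # Hadlock EFW through the log-scale elasticities (d log EFW / d log measure,
  # evaluated near 34 weeks): their sum E_TOT ~ 3.16 governs the common
  # (sonographer/caliper) error, their sum of squares E_SS ~ 3.73 the
  # independent per-measure errors. The common error SD is solved so the
  # total EFW CV equals efw_measurement_cv.
  E_TOT <- 3.16
  E_SS <- 3.73
  TRANS_BIO <- 0.026  # EFW CV contributed by transient biological variation
  s_i <- 0.015        # independent per-measure measurement error (fraction)
  s_c <- sqrt(pmax(p$efw_measurement_cv^2 - E_SS * s_i^2 - TRANS_BIO^2,
                   1e-5)) / E_TOT
  s_c_clin <- sqrt(s_c^2 + (p$clinical_extra_cv / E_TOT)^2)

  ethnicities <- c("white", "south_asian", "black", "other")

  # per-subject columns
  cols <- c("u", "z0", "fgr", "d", "sexM", "height", "weight", "age",
            "smoker", "eth", "miscarriage", "diabetes", "ga_del",
            "ga20", "ga28", "ga36", "has36", "eps_late", "sfh_noise",
            "u_ind", "n_clin", "clin_gap", "clin_gap2", "shape0",
            "uta_raw", "ua20_raw", "ua28_raw",
            "ua36_raw", "u_morb", "u_sev", "c_adm", "c_acid", "c_apg",
            "apgar_u", "ph_u", "bd_u", "adm_hr_u", "dis_hr_u",
            "s_vent", "s_ino", "s_hie", "s_acid", "s_death")
  M <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  # per-scan arrays: scan slots (20wk, 28wk, 36wk, last clinical, earlier
  # clinical) x measure (hc, ac, fl, bpd)
  delta <- array(NA_real_, c(n, 5, 4))   # transient biological variation
  eps_m <- array(NA_real_, c(n, 5, 4))   # independent measurement error
  eps_c <- matrix(NA_real_, n, 5)        # common (scan-level) measurement error

  for (i in seq_len(n)) {
    set.seed(as.integer((p$seed * 48271 + i * 2654435) %% 2147483563))
    M[i, "u"] <- stats::runif(1)
    M[i, "z0"] <- stats::qnorm(M[i, "u"])
    M[i, "fgr"] <- stats::runif(1) < p$fgr_latent_prevalence
    M[i, "d"] <- stats::rnorm(1, p$velocity_deficit, p$velocity_deficit_sd)
    M[i, "sexM"] <- stats::runif(1) < 0.5
    M[i, "height"] <- stats::rnorm(1, 164, 6.3)
    M[i, "weight"] <- max(40, stats::rnorm(1, 66, 12.5))
    M[i, "age"] <- min(45, max(16, stats::rnorm(1, 29.8, 5.1)))
    M[i, "smoker"] <- stats::runif(1) < 0.047
    M[i, "eth"] <- sample.int(4L, 1, prob = c(0.93, 0.03, 0.02, 0.02))
    M[i, "miscarriage"] <- stats::runif(1) < 0.102
    udb <- stats::runif(1)
    M[i, "diabetes"] <- if (udb < 0.0035) 2 else if (udb < 0.044) 1 else 0
    uga <- stats::runif(1)
    M[i, "ga_del"] <- if (uga < 0.008) stats::runif(1, 29, 33)
      else if (uga < 0.043) stats::runif(1, 33, 37)
      else min(42.2, max(37, stats::rnorm(1, 39.9, 1.15)))
    M[i, "ga20"] <- 20 + stats::runif(1, -0.85, 1.25)
    M[i, "ga28"] <- 28.1 + stats::runif(1, -0.8, 1.1)
    M[i, "ga36"] <- 36.1 + stats::runif(1, -0.8, 1.1)
    M[i, "eps_late"] <- stats::rnorm(1, 0, p$late_growth_sd)
    M[i, "sfh_noise"] <- stats::rnorm(1, 0, 0.6)
    M[i, "u_ind"] <- stats::runif(1)
    M[i, "n_clin"] <- sample.int(3L, 1, prob = c(0.55, 0.30, 0.15))
    M[i, "clin_gap"] <- 0.6 + stats::rgamma(1, shape = 2, scale = 1.5)
    M[i, "clin_gap2"] <- stats::runif(1, 1.5, 3.5)
    M[i, "shape0"] <- stats::rnorm(1, 0, 1.2)
    delta[i, , ] <- stats::rnorm(20, 0, 0.35)
    eps_m[i, , ] <- stats::rnorm(20)
    eps_c[i, ] <- stats::rnorm(5)
    M[i, "uta_raw"] <- stats::rnorm(1)
    M[i, c("ua20_raw", "ua28_raw", "ua36_raw")] <- stats::rnorm(3)
    M[i, c("u_morb", "u_sev", "c_adm", "c_acid", "c_apg")] <- stats::runif(5)
    M[i, c("apgar_u", "ph_u", "bd_u", "adm_hr_u", "dis_hr_u")] <- stats::runif(5)
    M[i, c("s_vent", "s_ino", "s_hie", "s_acid", "s_death")] <- stats::runif(5)
  }

  d <- as.data.frame(M)
  d$fgr <- d$fgr > 0
  d$ga_del <- pmax(d$ga_del, d$ga28 + 0.6)
  d$has36 <- d$ga_del > d$ga36 + 0.15

  z_growth <- function(ga) mu0 + d$z0 + ifelse(d$fgr, d$d * fgr_ramp(ga), 0)

  # --- birth size and gold standard -----------------------------------------
  z_del <- z_growth(d$ga_del) + d$eps_late
  sex <- ifelse(d$sexM > 0, "M", "F")
  bw <- bw_std$location(d$ga_del, sex) + z_del * bw_std$scale(d$ga_del, sex)
  bw <- pmax(bw, 250)
  sga_true <- 100 * stats::pnorm(z_del) < 10

  # --- clinically indicated scan selection ----------------------------------
  lp <- 4.5 * (d$diabetes > 0) + 1.2 * (d$weight / (d$height / 100)^2 >= 35) +
    0.6 * (d$age < 20 | d$age >= 40) + 0.35 * d$miscarriage +
    p$smallness_indication_coef * (-(z_growth(32) + d$sfh_noise))
  a_ind <- stats::uniroot(function(a) mean(stats::plogis(a + lp)) -
                            p$selective_scan_rate, c(-15, 15), tol = 1e-9)$root
  scanned <- d$u_ind < stats::plogis(a_ind + lp)
  ga_clin <- pmin(pmax(d$ga_del - d$clin_gap, 26.2), d$ga_del - 0.3, 41.5)
  ga_clin2 <- pmax(ga_clin - d$clin_gap2, 24.5)
  has_clin2 <- scanned & d$n_clin >= 2

  # --- per-scan measured EFW Z and biometry ---------------------------------
  scan_defs <- list(
    list(ga = d$ga20, keep = rep(TRUE, n), policy = "research20",
         slot = 1, shift = 0, sc = s_c),
    list(ga = d$ga28, keep = rep(TRUE, n), policy = "research28",
         slot = 2, shift = 0, sc = s_c),
    list(ga = d$ga36, keep = d$has36, policy = "research36",
         slot = 3, shift = 0, sc = s_c),
    list(ga = ga_clin2, keep = has_clin2, policy = "selective",
         slot = 5, shift = p$clinical_efw_shift, sc = s_c_clin),
    list(ga = ga_clin, keep = scanned, policy = "selective",
         slot = 4, shift = p$clinical_efw_shift, sc = s_c_clin)
  )
  # Per-measure composition at each scan: the common size factor lambda
  # (closed-form Hadlock inversion of the latent size), an EFW-neutral
  # persistent body-shape factor, a head-sparing FGR pattern (AC reduced,
  # head preserved), transient biological variation, and multiplicative
  # measurement error (common + per-measure).
  shape_frac <- c(hc = -0.036, ac = 0.040, fl = -0.042, bpd = -0.036)
  hs_frac <- c(hc = 0.015, ac = -0.050, fl = -0.010, bpd = 0.015)
  scans <- do.call(rbind, lapply(scan_defs, function(sd0) {
    k <- sd0$keep
    ga <- sd0$ga[k]
    z_clean <- z_growth(sd0$ga)[k] + sd0$shift - p$efw_standard_offset
    z_clean <- pmax(z_clean, -5.5)
    efw_target <- efw_std$location(ga) * (1 + 0.127 * z_clean)
    efw_target <- pmax(efw_target, 0.35 * efw_std$location(ga))
    med <- list(hc = bio$median$hc(ga), ac = bio$median$ac(ga),
                fl = bio$median$fl(ga), bpd = bio$median$bpd(ga))
    lam <- solve_biometry_lambda(efw_target, med$hc, med$ac, med$fl, eq)
    ramp <- fgr_ramp(ga)
    fgrk <- d$fgr[k]
    fs <- bio$frac_sd
    meas <- function(m, j) {
      med[[m]] * lam *
        (1 + shape_frac[[m]] * d$shape0[k] + hs_frac[[m]] * fgrk * ramp +
           fs[[m]] * delta[k, sd0$slot, j]) *
        exp(sd0$sc * eps_c[k, sd0$slot] + s_i * eps_m[k, sd0$slot, j])
    }
    uta <- ua <- rep(NA_real_, sum(k))
    if (sd0$policy == "research20")
      uta <- pmax(0.3, 1.62 + 0.55 * fgrk + 0.33 * d$uta_raw[k])
    if (sd0$policy %in% c("research20", "research28", "research36")) {
      ua_raw <- switch(sd0$policy, research20 = d$ua20_raw,
                       research28 = d$ua28_raw, research36 = d$ua36_raw)[k]
      ua <- pmax(0.25, 1.05 - 0.025 * (ga - 28) + 0.35 * fgrk * ramp +
                   0.16 * ua_raw)
    }
    data.frame(
      subject_id = which(k),
      scan_ga_weeks = round(ga, 2),
      scan_policy = sd0$policy,
      bpd_mm = round(cm_to_mm(meas("bpd", 4)), 1),
      hc_mm = round(cm_to_mm(meas("hc", 1)), 1),
      ac_mm = round(cm_to_mm(meas("ac", 2)), 1),
      fl_mm = round(cm_to_mm(meas("fl", 3)), 1),
      uta_pi_mean = round(uta, 3),
      ua_pi = round(ua, 3)
    )
  }))
  scans <- scans[order(scans$subject_id, scans$scan_ga_weeks), ]
  # rounded GAs can collide between a clinical and a research scan; nudge
  # duplicates so per-subject scan times are strictly increasing
  repeat {
    dup <- duplicated(scans[c("subject_id", "scan_ga_weeks")])
    if (!any(dup)) break
    scans$scan_ga_weeks[dup] <- scans$scan_ga_weeks[dup] + 0.01
    scans <- scans[order(scans$subject_id, scans$scan_ga_weeks), ]
  }
  rownames(scans) <- NULL

  # --- neonatal morbidity ----------------------------------------------------
  beta_sga <- 0.15
  cal_morb <- calibrate_logistic(p$morbidity_base_rate,
                                 p$rr_morbidity_given_sga_lowvelocity,
                                 d$fgr, sga_true, beta_sga)
  morb <- d$u_morb < stats::plogis(cal_morb$alpha + cal_morb$beta_fgr * d$fgr +
                                     beta_sga * sga_true)
  term <- d$ga_del >= 37
  sev_lp <- 1.1 * d$fgr + 0.7 * sga_true
  a_sev <- stats::uniroot(function(a) mean(stats::plogis(a + sev_lp) * term) -
                            p$severe_adverse_rate, c(-15, 5), tol = 1e-9)$root
  severe <- term & (d$u_sev < stats::plogis(a_sev + sev_lp))

  comp_adm <- morb & term & d$c_adm < 0.833
  comp_acid <- morb & d$c_acid < 0.153
  comp_apg <- morb & d$c_apg < 0.131
  none <- morb & !(comp_adm | comp_acid | comp_apg)
  comp_adm[none & term] <- TRUE
  comp_acid[none & !term] <- TRUE

  sv <- severe & d$s_vent < 0.5
  si <- severe & d$s_ino < 0.3
  sh <- severe & d$s_hie < 0.2
  sa <- severe & d$s_acid < 0.35
  sd_ <- severe & d$s_death < 0.05
  s_none <- severe & !(sv | si | sh | sa | sd_)
  sv[s_none] <- TRUE

  ph <- 7.05 + 0.40 * d$ph_u            # benign default range 7.05-7.45
  bd <- 9.8 * d$bd_u                    # benign default < 10
  ph[comp_acid] <- 7.00 + 0.09 * d$ph_u[comp_acid]
  bd[comp_acid] <- 10.2 + 4.8 * d$bd_u[comp_acid]
  ph[sa] <- 6.82 + 0.17 * d$ph_u[sa]
  bd[sa] <- 12.2 + 5.8 * d$bd_u[sa]

  apgar5 <- 8 + round(2 * d$apgar_u)
  apgar5[comp_apg] <- 3 + round(3 * d$apgar_u[comp_apg])

  nnu <- comp_adm | (!term & d$adm_hr_u < 0.7) | (term & !morb & d$adm_hr_u < 0.02)
  admit_hr <- rep(NA_real_, n)
  dis_hr <- rep(NA_real_, n)
  admit_hr[nnu] <- round(1 + 39 * d$adm_hr_u[nnu], 1)
  dis_hr[nnu] <- round(50 + 350 * d$dis_hr_u[nnu], 1)
  short <- nnu & term & !comp_adm
  dis_hr[short] <- round(4 + 40 * d$dis_hr_u[short], 1)

  ids <- seq_len(n)
  maternal <- data.frame(
    subject_id = ids,
    age_years = round(d$age, 1),
    height_cm = round(d$height, 1),
    weight_kg = round(d$weight, 1),
    bmi = round(d$weight / (d$height / 100)^2, 1),
    ethnicity = ethnicities[d$eth],
    smoker = d$smoker > 0,
    parity = 0L,
    diabetes = c("none", "gestational", "pregestational")[d$diabetes + 1]
  )
  outcomes <- data.frame(
    subject_id = ids,
    ga_delivery_weeks = round(d$ga_del, 2),
    birthweight_g = round(bw),
    sex = sex,
    apgar5 = as.integer(apgar5),
    cord_ph = round(ph, 2),
    cord_base_deficit = round(bd, 1),
    nnu_admission = nnu,
    nnu_admit_hours = admit_hr,
    nnu_discharge_hours = dis_hr,
    stillbirth = FALSE,
    neonatal_death = sd_,
    hie = sh,
    inotropes = si,
    mechanical_ventilation = sv
  )
  truth <- data.frame(
    subject_id = ids,
    latent_percentile = d$u,
    fgr_class = d$fgr,
    z_birth = z_del,
    sga_true = sga_true,
    morbidity_true = morb,
    severe_true = severe,
    scanned_selective = scanned
  )
  attr(truth, "calibration") <- list(mu0 = mu0, indication_intercept = a_ind,
                                     morbidity = cal_morb,
                                     severe_intercept = a_sev)
  structure(list(maternal = maternal, scans = scans, outcomes = outcomes,
                 truth = truth, params = p),
            class = "fg_cohort")
}

# Solve the logistic intercept and FGR effect jointly so that the marginal
# morbidity rate and the FGR-vs-non-FGR risk ratio both hit their targets.
calibrate_logistic <- function(base_rate, rr, fgr, sga, beta_sga) {
  f <- function(alpha) {
    p_ref <- mean(stats::plogis(alpha + beta_sga * sga[!fgr]))
    p_hi <- min(rr * p_ref, 0.99)
    beta_fgr <- stats::qlogis(p_hi) - alpha - beta_sga
    mean(stats::plogis(alpha + beta_fgr * fgr + beta_sga * sga)) - base_rate
  }
  alpha <- tryCatch(stats::uniroot(f, c(-12, 3), tol = 1e-9)$root,
                    error = function(e)
                      stop_gs("cannot calibrate morbidity model: base rate %g with risk ratio %g is infeasible",
                              base_rate, rr, class = "gs_calibration_error"))
  p_ref <- mean(stats::plogis(alpha + beta_sga * sga[!fgr]))
  p_hi <- rr * p_ref
  if (p_hi >= 0.95)
    stop_gs("risk ratio %g unreachable at base rate %g (implied stratum risk %.2f)",
            rr, base_rate, p_hi, class = "gs_calibration_error")
  list(alpha = alpha, beta_sga = beta_sga,
       beta_fgr = stats::qlogis(p_hi) - alpha - beta_sga)
}

#' Latent-class ledger of a synthetic cohort
#'
#' Returns the per-subject latent state (true growth percentile, FGR class,
#' birth Z-score, true SGA/morbidity status) for parameter-recovery checks.
#' Analysis stages never consume this table.
#'
#' @param cohort an `fg_cohort` from [generate_cohort()].
#' @return data frame with one row per subject.
#' @export
truth_table <- function(cohort) {
  stopifnot(inherits(cohort, "fg_cohort"))
  cohort$truth
}

#' Write / read a cohort as CSV tables
#'
#' @param cohort an `fg_cohort`.
#' @param dir output directory (created if missing).
#' @return `write_cohort` returns the directory invisibly; `read_cohort`
#'   returns a list with `maternal`, `scans`, `outcomes`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("maternal", "scans", "outcomes"))
    utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  read1 <- function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path))
      stop_gs("cohort file '%s' not found", path, class = "gs_io_error")
    utils::read.csv(path)
  }
  list(maternal = read1("maternal"), scans = read1("scans"),
       outcomes = read1("outcomes"))
}
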