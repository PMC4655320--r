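#' Gold-standard SGA classification from a birthweight percentile
#'
#' SGA is a birthweight strictly below the 10th percentile for gestational
#' age and sex; severe SGA strictly below the 3rd. Thresholds are strict
#' (`<`): a percentile exactly at the cut is not SGA.
#'
#' @param bw_percentile birthweight percentile in (0, 100).
#' @param threshold SGA percentile threshold (default 10).
#' @param severe_threshold severe-SGA threshold (default 3).
#' @return data frame with logical columns `sga`, `severe_sga`.
#' @export
gold_standard <- function(bw_percentile, threshold = 10, severe_threshold = 3) {
  stopifnot(all(bw_percentile > 0 & bw_percentile < 100, na.rm = TRUE))
  data.frame(sga = bw_percentile < threshold,
             severe_sga = bw_percentile < severe_threshold)
}

#' Composite neonatal outcome flags
#'
#' Composite neonatal morbidity is one or more of: 5-minute Apgar below 7;
#' metabolic acidosis (cord pH < 7.1 and base deficit > 10 mmol/L, both
#' strict); neonatal-unit admission at term (admission < 48 h after birth at
#' >= 37 weeks with discharge >= 48 h after admission). The severe adverse
#' composite is stillbirth, or a term livebirth with neonatal death, hypoxic
#' ischaemic encephalopathy, inotrope use, mechanical ventilation, or severe
#' metabolic acidosis (pH < 7.0 and base deficit > 12 mmol/L). Missing
#' component fields are treated as criterion-not-met and counted in the
#' `missing_log` attribute.
#'
#' @param outcomes data frame with columns `ga_delivery_weeks`, `apgar5`,
#'   `cord_ph`, `cord_base_deficit`, `nnu_admission`, `nnu_admit_hours`,
#'   `nnu_discharge_hours`, and logical severe-component columns
#'   (`stillbirth`, `neonatal_death`, `hie`, `inotropes`,
#'   `mechanical_ventilation`).
#' @return data frame of logical flags (`metabolic_acidosis`, `low_apgar5`,
#'   `nnu_admission_term`, `neonatal_morbidity`, `severe_adverse`) with a
#'   `missing_log` attribute.
#' @export
neonatal_morbidity <- function(outcomes) {
  o <- outcomes
  if (any(o$nnu_discharge_hours < 0, na.rm = TRUE))
    stop_gs("neonatal-unit discharge before admission (negative duration)",
            class = "gs_validation_error")
  na_false <- function(x) !is.na(x) & x
  term <- na_false(o$ga_delivery_weeks >= 37)
  acid <- na_false(o$cord_ph < 7.1 & o$cord_base_deficit > 10)
  apg <- na_false(o$apgar5 < 7)
  adm <- na_false(o$nnu_admission) & term &
    na_false(o$nnu_admit_hours < 48) & na_false(o$nnu_discharge_hours >= 48)
  sev_acid <- na_false(o$cord_ph < 7.0 & o$cord_base_deficit > 12)
  sev <- na_false(o$stillbirth) |
    (term & (na_false(o$neonatal_death) | na_false(o$hie) |
               na_false(o$inotropes) | na_false(o$mechanical_ventilation) |
               sev_acid))
  flags <- data.frame(
    metabolic_acidosis = acid,
    low_apgar5 = apg,
    nnu_admission_term = adm,
    neonatal_morbidity = acid | apg | adm,
    severe_adverse = sev
  )
  miss_cols <- c("apgar5", "cord_ph", "cord_base_deficit", "nnu_admission")
  attr(flags, "missing_log") <-
    vapply(miss_cols, function(cn) sum(is.na(o[[cn]])), integer(1))
  flags
}

#' Classify one pregnancy under a screening policy
#'
#' Screening status is based on the last eligible scan before birth. Under
#' the selective policy, eligible scans are clinically indicated scans at a
#' gestational age of `ga_cutoff` (26) weeks or later; a woman with no such
#' scan is screen negative by definition. Under the universal policy,
#' eligible scans are the research scans at 28 or 36 weeks. Screen positive
#' is an EFW percentile strictly below `threshold`; a percentile exactly at
#' the threshold is screen negative.
#'
#' @param scans data frame of one subject's scans with columns
#'   `scan_ga_weeks`, `scan_policy`, `hc_mm`, `ac_mm`, `fl_mm`.
#' @param ga_delivery gestational age at delivery (weeks).
#' @param policy `"selective"` or `"universal"`.
#' @param threshold screen-positive percentile threshold.
#' @param ga_cutoff minimum GA for a clinically indicated scan to count.
#' @param standard EFW-for-GA `growth_standard`.
#' @return list with `status` (`"positive"`/`"negative"`), `efw_percentile`,
#'   `efw_g`, and `scan_ga_weeks` (all `NA` when no eligible scan exists).
#' @export
classify_policy <- function(scans, ga_delivery,
                            policy = c("selective", "universal"),
                            threshold = 10, ga_cutoff = 26,
                            standard = fg_standard("hadlock1991_efw_ga")) {
  policy <- match.arg(policy)
  s <- scans[order(scans$scan_ga_weeks), , drop = FALSE]
  s <- s[s$scan_ga_weeks < ga_delivery, , drop = FALSE]
  elig <- if (policy == "selective") {
    s$scan_policy == "selective" & s$scan_ga_weeks >= ga_cutoff
  } else {
    s$scan_policy %in% c("research28", "research36")
  }
  s <- s[elig, , drop = FALSE]
  if (nrow(s) == 0) {
    if (policy == "selective")
      return(list(status = "negative", efw_percentile = NA_real_,
                  efw_g = NA_real_, scan_ga_weeks = NA_real_))
    stop_gs("no research scan at 28 weeks or later before delivery; subject is excluded from universal screening (mirrors exclusion of pre-28-week deliveries)",
            class = "gs_exclusion_error")
  }
  last <- s[nrow(s), ]
  efw <- hadlock_efw(mm_to_cm(last$hc_mm), mm_to_cm(last$ac_mm),
                     mm_to_cm(last$fl_mm))
  pct <- efw_percentile(efw, last$scan_ga_weeks, standard)
  list(status = if (pct < threshold) "positive" else "negative",
       efw_percentile = pct, efw_g = efw, scan_ga_weeks = last$scan_ga_weeks)
}

#' Flag the extreme decile of a cohort distribution
#'
#' Decile cuts use the standard empirical quantile (type 7) over all
#' non-missing values; a value is flagged only when strictly beyond the cut,
#' so ties at the cut are never flagged (matching the strict-inequality
#' convention of the screen-positive rule). Missing values are flagged
#' `FALSE` and counted in the `n_missing` attribute.
#'
#' @param values numeric cohort vector.
#' @param tail `"lowest"` or `"highest"`.
#' @return logical vector with attributes `cut` and `n_missing`.
#' @export
decile_flags <- function(values, tail = c("lowest", "highest")) {
  tail <- match.arg(tail)
  ok <- !is.na(values)
  if (sum(ok) < 10)
    stop_gs("need at least 10 non-missing values to form deciles (have %d)",
            sum(ok), class = "gs_missing_input")
  cut <- stats::quantile(values[ok], if (tail == "lowest") 0.10 else 0.90,
                         type = 7, names = FALSE)
  flag <- if (tail == "lowest") values < cut else values > cut
  flag[!ok] <- FALSE
  structure(flag, cut = cut, n_missing = sum(!ok))
}

# last eligible scan index per subject for a vectorised policy classification
last_scan_index <- function(scans, ga_delivery_by_id, eligible) {
  before <- scans$scan_ga_weeks < ga_delivery_by_id[as.character(scans$subject_id)]
  keep <- which(eligible & before)
  if (length(keep) == 0) return(integer(0))
  k <- keep[order(scans$subject_id[keep], scans$scan_ga_weeks[keep])]
  k[!duplicated(scans$subject_id[k], fromLast = TRUE)]
}

#' Classify a whole cohort
#'
#' Runs the full classification stage: EFW percentiles and screen status per
#' policy, gold-standard SGA from birthweight, composite outcome flags,
#' within-cohort GA-adjusted Z-score models for the growth-restriction
#' markers, abdominal-circumference growth velocity, and cohort decile flags
#' for the five markers (highest decile of HC/AC ratio, uterine and umbilical
#' pulsatility index; lowest decile of AC/FL ratio and AC growth velocity).
#' Marker measurements come from the research scans (last before birth,
#' except the uterine Doppler which is classified at the 20-week scan).
#'
#' @param scans,outcomes,maternal cohort tables as produced by
#'   [generate_cohort()] (or read from CSV with the same schema).
#' @param threshold,severe_threshold,ga_cutoff classification settings.
#' @param efw_standard,bw_standard growth standards.
#' @param customisation customisation coefficients, or `NULL` to skip the
#'   customised percentile.
#' @param zscore_degree polynomial degree of the Z-score models.
#' @return data frame with one row per subject: screen statuses and EFW
#'   percentiles per policy, customised percentile, birthweight percentile,
#'   `sga`/`severe_sga`, outcome flags, marker values and decile flags. The
#'   `log` attribute records exclusions and missing counts.
#' @export
classify_cohort <- function(scans, outcomes, maternal = NULL,
                            threshold = 10, severe_threshold = 3,
                            ga_cutoff = 26,
                            efw_standard = fg_standard("hadlock1991_efw_ga"),
                            bw_standard = fg_standard("birthweight_uk_synthetic"),
                            customisation = fg_customisation(),
                            zscore_degree = 2) {
  if (inherits(scans, "fg_cohort")) {
    cohort <- scans
    scans <- cohort$scans; outcomes <- cohort$outcomes
    maternal <- cohort$maternal
  }
  outcomes <- outcomes[order(outcomes$subject_id), ]
  scans <- scans[order(scans$subject_id, scans$scan_ga_weeks), ]
  ids <- outcomes$subject_id
  n <- length(ids)
  ga_del <- stats::setNames(outcomes$ga_delivery_weeks, ids)
  log <- list()

  efw_g <- hadlock_efw(mm_to_cm(scans$hc_mm), mm_to_cm(scans$ac_mm),
                       mm_to_cm(scans$fl_mm))
  efw_pct <- efw_percentile(efw_g, scans$scan_ga_weeks, efw_standard)

  # universal: last research scan (28/36wk policy) before birth
  i_uni <- last_scan_index(scans, ga_del,
                           scans$scan_policy %in% c("research28", "research36"))
  uni <- data.frame(subject_id = scans$subject_id[i_uni],
                    universal_efw_percentile = efw_pct[i_uni],
                    universal_efw_g = efw_g[i_uni],
                    universal_scan_ga = scans$scan_ga_weeks[i_uni])
  missing_uni <- setdiff(ids, uni$subject_id)
  if (length(missing_uni) > 0) {
    log$excluded_no_research_scan <- missing_uni
    ids <- setdiff(ids, missing_uni)
    outcomes <- outcomes[outcomes$subject_id %in% ids, ]
    ga_del <- ga_del[as.character(ids)]
    n <- length(ids)
  }

  # selective: last clinically indicated scan at >= ga_cutoff before birth
  i_sel <- last_scan_index(scans, ga_del,
                           scans$scan_policy == "selective" &
                             scans$scan_ga_weeks >= ga_cutoff)
  sel <- data.frame(subject_id = scans$subject_id[i_sel],
                    selective_efw_percentile = efw_pct[i_sel],
                    selective_scan_ga = scans$scan_ga_weeks[i_sel])

  cls <- data.frame(subject_id = ids)
  cls <- merge(cls, uni, by = "subject_id", all.x = TRUE)
  cls <- merge(cls, sel, by = "subject_id", all.x = TRUE)
  cls <- cls[order(cls$subject_id), ]
  cls$universal_status <- ifelse(cls$universal_efw_percentile < threshold,
                                 "positive", "negative")
  cls$selective_status <- ifelse(!is.na(cls$selective_efw_percentile) &
                                   cls$selective_efw_percentile < threshold,
                                 "positive", "negative")

  # customised percentile of the last universal EFW
  if (!is.null(customisation) && !is.null(maternal)) {
    m <- maternal[match(cls$subject_id, maternal$subject_id), ]
    cls$customised_efw_percentile <- customised_percentile(
      cls$universal_efw_g, cls$universal_scan_ga,
      height_cm = m$height_cm, weight_kg = m$weight_kg,
      ethnicity = m$ethnicity, smoker = m$smoker,
      coefs = customisation, standard = efw_standard)
    cls$customised_status <- ifelse(cls$customised_efw_percentile < threshold,
                                    "positive", "negative")
  }

  # gold standard from birthweight
  cls$bw_percentile <- birthweight_percentile(outcomes$birthweight_g,
                                              outcomes$ga_delivery_weeks,
                                              outcomes$sex, bw_standard)
  gs <- gold_standard(cls$bw_percentile, threshold, severe_threshold)
  cls$sga <- gs$sga
  cls$severe_sga <- gs$severe_sga

  # outcome flags
  flags <- neonatal_morbidity(outcomes)
  log$missing_outcome_fields <- attr(flags, "missing_log")
  cls <- cbind(cls, flags)
  cls$sga_plus_morbidity <- cls$sga & cls$neonatal_morbidity
  cls$sga_plus_severe <- cls$sga & cls$severe_adverse

  # growth-restriction markers from research scans, as GA-adjusted Z-scores
  res <- scans[scans$scan_policy %in% c("research20", "research28", "research36") &
                 scans$subject_id %in% ids, ]
  res$ac_cm <- mm_to_cm(res$ac_mm)
  res$hc_ac <- res$hc_mm / res$ac_mm
  res$ac_fl <- res$ac_mm / res$fl_mm
  zfit <- function(value, sub = rep(TRUE, nrow(res)), degree = zscore_degree)
    fit_zscore_model(res$scan_ga_weeks[sub], value[sub], degree = degree)

  zm_ac <- zfit(res$ac_cm)
  zm_hcac <- zfit(res$hc_ac)
  zm_acfl <- zfit(res$ac_fl)
  ok_ua <- !is.na(res$ua_pi)
  zm_ua <- zfit(res$ua_pi, ok_ua)
  is20 <- res$scan_policy == "research20" & !is.na(res$uta_pi_mean)
  zm_uta <- fit_zscore_model(res$scan_ga_weeks[is20], res$uta_pi_mean[is20],
                             degree = 1)

  i_last <- last_scan_index(res, ga_del, rep(TRUE, nrow(res)))
  i_20 <- which(res$scan_policy == "research20")
  at <- function(idx, model, col) {
    z <- zscore(model, res$scan_ga_weeks[idx], res[[col]][idx])
    stats::setNames(z, res$subject_id[idx])[as.character(cls$subject_id)]
  }
  z_ac_last <- at(i_last, zm_ac, "ac_cm")
  z_ac_20 <- at(i_20, zm_ac, "ac_cm")
  cls$acgv <- unname(z_ac_last - z_ac_20)
  log$acgv_missing <- sum(is.na(cls$acgv))
  cls$hc_ac_z <- unname(at(i_last, zm_hcac, "hc_ac"))
  cls$ac_fl_z <- unname(at(i_last, zm_acfl, "ac_fl"))
  i_last_ua <- last_scan_index(res, ga_del, ok_ua)
  cls$ua_pi_z <- unname(at(i_last_ua, zm_ua, "ua_pi"))
  cls$uta_pi_z <- unname(at(which(is20), zm_uta, "uta_pi_mean"))

  cls$hc_ac_top_decile <- as.logical(decile_flags(cls$hc_ac_z, "highest"))
  cls$ac_fl_bottom_decile <- as.logical(decile_flags(cls$ac_fl_z, "lowest"))
  cls$uta_top_decile <- as.logical(decile_flags(cls$uta_pi_z, "highest"))
  cls$ua_top_decile <- as.logical(decile_flags(cls$ua_pi_z, "highest"))
  cls$acgv_bottom_decile <- as.logical(decile_flags(cls$acgv, "lowest"))

  rownames(cls) <- NULL
  attr(cls, "log") <- log
  attr(cls, "zscore_models") <- list(ac = zm_ac, hc_ac = zm_hcac,
                                     ac_fl = zm_acfl, ua = zm_ua, uta = zm_uta)
  cls
}
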