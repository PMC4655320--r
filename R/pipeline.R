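#' Validate cohort input tables
#'
#' Schema and sanity checks for the scan/outcome/maternal CSV tables:
#' required columns, gestational-age ranges, positive biometry with
#' millimetre-scale magnitudes, per-subject scan ordering, and delivery
#' after the last scan. Problems are returned as rows, not raised, so a
#' caller can distinguish warnings from errors.
#'
#' @param scans,outcomes,maternal cohort tables (maternal optional).
#' @return data frame with columns `severity` (`"error"`/`"warning"`),
#'   `subject_id`, `field`, `message`; zero rows when everything passes.
#'   Attribute `ok` is `TRUE` when no errors.
#' @export
validate_cohort <- function(scans, outcomes, maternal = NULL) {
  probs <- list()
  add <- function(severity, subject_id, field, message)
    probs[[length(probs) + 1]] <<- data.frame(
      severity = severity, subject_id = as.character(subject_id),
      field = field, message = message)

  need_scan <- c("subject_id", "scan_ga_weeks", "scan_policy", "hc_mm",
                 "ac_mm", "fl_mm")
  need_out <- c("subject_id", "ga_delivery_weeks", "birthweight_g", "sex")
  for (cn in setdiff(need_scan, names(scans)))
    add("error", NA, cn, sprintf("scans: missing required column '%s'", cn))
  for (cn in setdiff(need_out, names(outcomes)))
    add("error", NA, cn, sprintf("outcomes: missing required column '%s'", cn))
  if (length(probs) > 0) {
    out <- do.call(rbind, probs)
    attr(out, "ok") <- FALSE
    return(out)
  }

  for (m in c("bpd_mm", "hc_mm", "ac_mm", "fl_mm")) {
    if (!m %in% names(scans)) next
    bad <- which(!is.na(scans[[m]]) & scans[[m]] <= 0)
    for (i in bad)
      add("error", scans$subject_id[i], m,
          sprintf("nonpositive %s (%g) for subject %s", m, scans[[m]][i],
                  scans$subject_id[i]))
    med <- stats::median(scans[[m]], na.rm = TRUE)
    if (is.finite(med) && med < 40 && m != "fl_mm")
      add("warning", NA, m,
          sprintf("median %s = %g looks like cm, expected mm", m, med))
  }
  bad_ga <- which(scans$scan_ga_weeks < 12 | scans$scan_ga_weeks > 43)
  for (i in bad_ga)
    add("error", scans$subject_id[i], "scan_ga_weeks",
        sprintf("scan GA %g outside [12, 43] for subject %s",
                scans$scan_ga_weeks[i], scans$subject_id[i]))

  dup <- tapply(scans$scan_ga_weeks, scans$subject_id,
                function(g) any(duplicated(g)))
  for (sid in names(dup)[which(dup)])
    add("warning", sid, "scan_ga_weeks",
        sprintf("duplicate scan gestational ages for subject %s", sid))

  last_ga <- tapply(scans$scan_ga_weeks, scans$subject_id, max)
  del_ga <- stats::setNames(outcomes$ga_delivery_weeks,
                            as.character(outcomes$subject_id))
  common <- intersect(names(last_ga), names(del_ga))
  late <- common[del_ga[common] <= last_ga[common]]
  for (sid in late)
    add("error", sid, "ga_delivery_weeks",
        sprintf("delivery GA (%g) not after last scan GA (%g) for subject %s",
                del_ga[sid], last_ga[sid], sid))

  bad_bw <- which(!is.na(outcomes$birthweight_g) & outcomes$birthweight_g <= 0)
  for (i in bad_bw)
    add("error", outcomes$subject_id[i], "birthweight_g",
        sprintf("nonpositive birthweight for subject %s",
                outcomes$subject_id[i]))
  if ("apgar5" %in% names(outcomes)) {
    bad <- which(!is.na(outcomes$apgar5) &
                   (outcomes$apgar5 < 0 | outcomes$apgar5 > 10))
    for (i in bad)
      add("error", outcomes$subject_id[i], "apgar5",
          sprintf("Apgar score %g out of range for subject %s",
                  outcomes$apgar5[i], outcomes$subject_id[i]))
  }

  out <- if (length(probs) > 0) do.call(rbind, probs) else
    data.frame(severity = character(), subject_id = character(),
               field = character(), message = character())
  attr(out, "ok") <- !any(out$severity == "error")
  out
}

normalise_config <- function(config, ...) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    if (!is.null(config$params)) config$params <- do.call(cohort_params,
                                                          config$params)
  }
  config <- utils::modifyList(config %||% list(), list(...))
  defaults <- list(mode = "synthetic", seed = 1L, threshold = 10,
                   severe_threshold = 3, ga_cutoff = 26, out_dir = NULL,
                   input_dir = NULL, params = NULL)
  config <- utils::modifyList(defaults, config)
  if (!config$mode %in% c("synthetic", "csv"))
    stop_gs("mode must be 'synthetic' or 'csv'", class = "gs_config_error")
  if (!(config$threshold > 0 && config$threshold < 100) ||
      !(config$severe_threshold > 0 && config$severe_threshold < 100))
    stop_gs("percentile thresholds must be in (0, 100)",
            class = "gs_config_error")
  if (config$ga_cutoff < 20)
    stop_gs("clinical-scan GA cutoff must be at least 20 weeks",
            class = "gs_config_error")
  if (config$mode == "synthetic" && is.null(config$params))
    config$params <- cohort_params(seed = config$seed)
  if (config$mode == "csv" && is.null(config$input_dir))
    stop_gs("csv mode needs input_dir", class = "gs_config_error")
  config
}

#' Run the full screening analysis pipeline
#'
#' Stage order is fixed: synthesize or ingest a cohort, validate it,
#' classify (standards, Z-scores, deciles), compute the paired
#' diagnostic-accuracy comparison for SGA and severe SGA, then the
#' stratified relative-risk and interaction analyses. When `out_dir` is set,
#' the report bundle is written there: `screening_counts.csv`,
#' `diagnostic_accuracy_sga.csv`, `diagnostic_accuracy_severe_sga.csv`,
#' `risk_stratification.csv`, `stratified_markers.csv`, `estimates.json`
#' (full precision) and `run_log.txt`; every file records the config hash
#' and seed. On any stage error, partial outputs are removed and the error
#' re-raised.
#'
#' @param config a list (or YAML file path) with elements `mode`
#'   (`"synthetic"` or `"csv"`), `params` ([cohort_params()]; synthetic
#'   mode), `input_dir` (csv mode), `out_dir`, `seed`, `threshold`,
#'   `severe_threshold`, `ga_cutoff`.
#' @param ... overrides merged over `config`.
#' @return (invisibly) a list with the classification table, the paired
#'   data, accuracy reports, risk tables, marker-stratified estimates, the
#'   run log and the config.
#' @export
run_pipeline <- function(config = NULL, ...) {
  cfg <- normalise_config(config, ...)
  log_lines <- character()
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  cfg_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  note("config_hash: %s", cfg_hash)
  note("seed: %d", cfg$seed)

  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    if (cfg$mode == "synthetic") {
      cohort <- generate_cohort(cfg$params)
      tables <- cohort[c("maternal", "scans", "outcomes")]
      note("stage synthesize: %d subjects, %d scans",
           nrow(tables$outcomes), nrow(tables$scans))
    } else {
      tables <- read_cohort(cfg$input_dir)
      note("stage ingest: %d subjects, %d scans from %s",
           nrow(tables$outcomes), nrow(tables$scans), cfg$input_dir)
    }

    val <- validate_cohort(tables$scans, tables$outcomes, tables$maternal)
    n_err <- sum(val$severity == "error")
    note("stage validate: %d errors, %d warnings", n_err,
         sum(val$severity == "warning"))
    if (n_err > 0)
      stop_gs("input validation failed with %d error(s); first: %s", n_err,
              val$message[val$severity == "error"][1],
              class = "gs_validation_error")

    cls <- classify_cohort(tables$scans, tables$outcomes, tables$maternal,
                           threshold = cfg$threshold,
                           severe_threshold = cfg$severe_threshold,
                           ga_cutoff = cfg$ga_cutoff)
    note("stage classify: %d subjects classified, %d screen positive (universal), %d SGA",
         nrow(cls), sum(cls$universal_status == "positive"), sum(cls$sga))

    psd <- paired_screen_data(cls$selective_status, cls$universal_status,
                              cls$sga)
    psd_sev <- paired_screen_data(cls$selective_status, cls$universal_status,
                                  cls$severe_sga)
    acc <- accuracy_report(psd)
    acc_sev <- accuracy_report(psd_sev)
    note("stage accuracy: paired tables built (n = %d)", sum(psd))

    risk <- table4_report(cls)
    markers <- marker_strata_report(cls)
    note("stage risk: %d stratified estimates", nrow(risk) + nrow(markers))

    counts <- screening_counts(cls)

    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      wr <- function(obj, name) {
        path <- file.path(cfg$out_dir, name)
        utils::write.csv(cbind(obj, config_hash = cfg_hash, seed = cfg$seed),
                         path, row.names = FALSE)
        written <<- c(written, path)
      }
      wr(counts, "screening_counts.csv")
      wr(acc, "diagnostic_accuracy_sga.csv")
      wr(acc_sev, "diagnostic_accuracy_severe_sga.csv")
      wr(risk, "risk_stratification.csv")
      wr(markers, "stratified_markers.csv")
      est_path <- file.path(cfg$out_dir, "estimates.json")
      jsonlite::write_json(list(
        config_hash = cfg_hash, seed = cfg$seed,
        accuracy_sga = attr(acc, "summaries"),
        accuracy_severe_sga = attr(acc_sev, "summaries"),
        risk = risk, markers = markers
      ), est_path, auto_unbox = TRUE, digits = NA, force = TRUE)
      written <- c(written, est_path)
      log_path <- file.path(cfg$out_dir, "run_log.txt")
      writeLines(log_lines, log_path)
      written <- c(written, log_path)
    }

    invisible(list(classification = cls, paired_sga = psd,
                   paired_severe_sga = psd_sev, accuracy_sga = acc,
                   accuracy_severe_sga = acc_sev, risk = risk,
                   markers = markers, counts = counts, log = log_lines,
                   config = cfg, validation = val))
  }, error = on_fail)
}

#' Screening-effectiveness counts table
#'
#' The 2x2 counts of each policy against SGA and severe SGA, in the layout
#' screening papers print (policy blocks of screen positive / negative rows
#' with totals).
#'
#' @param cls classification data frame from [classify_cohort()].
#' @return data frame of counts.
#' @export
screening_counts <- function(cls) {
  block <- function(status, disease, policy, label) {
    pos <- status == "positive"
    data.frame(policy = policy, row = c("efw_lt10", "efw_ge10_or_no_scan",
                                        "total"),
               yes = c(sum(pos & disease), sum(!pos & disease), sum(disease)),
               no = c(sum(pos & !disease), sum(!pos & !disease),
                      sum(!disease)),
               total = c(sum(pos), sum(!pos), length(pos)),
               outcome = label)
  }
  rbind(block(cls$selective_status, cls$sga, "selective", "sga"),
        block(cls$universal_status, cls$sga, "universal", "sga"),
        block(cls$selective_status, cls$severe_sga, "selective", "severe_sga"),
        block(cls$universal_status, cls$severe_sga, "universal", "severe_sga"))
}

#' Marker-stratified screening risk estimates
#'
#' For each ultrasonic growth-restriction marker, the relative risk of
#' neonatal morbidity associated with a positive universal screen is
#' estimated separately in the marker-normal and marker-abnormal strata,
#' with a risk-ratio homogeneity (interaction) p-value and its logistic
#' cross-check.
#'
#' @param cls classification data frame from [classify_cohort()].
#' @return data frame with one row per marker.
#' @export
marker_strata_report <- function(cls) {
  markers <- c(hc_ac_top_decile = "hc_ac_top_decile",
               ac_fl_bottom_decile = "ac_fl_bottom_decile",
               uta_top_decile = "uta_top_decile",
               ua_top_decile = "ua_top_decile",
               acgv_bottom_decile = "acgv_bottom_decile")
  pos <- cls$universal_status == "positive"
  out <- lapply(names(markers), function(mn) {
    flag <- cls[[mn]]
    keep <- !is.na(flag)
    t_norm <- risk_table(pos[keep & !flag], cls$neonatal_morbidity[keep & !flag])
    t_abn <- risk_table(pos[keep & flag], cls$neonatal_morbidity[keep & flag])
    rr_n <- tryCatch(relative_risk(t_norm),
                     growthscreen_error = function(e) NULL)
    rr_a <- tryCatch(relative_risk(t_abn),
                     growthscreen_error = function(e) NULL)
    int <- tryCatch(mh_interaction(t_norm, t_abn),
                    growthscreen_error = function(e) NULL)
    data.frame(marker = mn,
               rr_normal = rr_n$rr %||% NA_real_,
               rr_normal_lower = rr_n$lower %||% NA_real_,
               rr_normal_upper = rr_n$upper %||% NA_real_,
               rr_abnormal = rr_a$rr %||% NA_real_,
               rr_abnormal_lower = rr_a$lower %||% NA_real_,
               rr_abnormal_upper = rr_a$upper %||% NA_real_,
               p_interaction = int$p %||% NA_real_,
               p_interaction_logistic = int$p_logistic %||% NA_real_)
  })
  do.call(rbind, out)
}
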