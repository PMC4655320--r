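#' Relative risk from a 2x2 table with Katz CI and Fisher exact p
#'
#' The table is exposure (rows: exposed, unexposed) by outcome (columns:
#' event, no event). The CI uses the Katz log method; when a zero cell makes
#' the log SE undefined, 0.5 is added to every cell *for the CI only* (the
#' point estimate is never corrected) and the `continuity` flag is set. The
#' two-sided Fisher p-value sums hypergeometric probabilities no larger than
#' that of the observed table.
#'
#' @param tab 2x2 numeric matrix of counts.
#' @param conf confidence level.
#' @return list with `rr`, `lower`, `upper`, `p_fisher`, risks per arm,
#'   and a `continuity` flag.
#' @export
relative_risk <- function(tab, conf = 0.95) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n1 <- a + b; n0 <- c + d
  if (n1 == 0 || n0 == 0)
    stop_gs("both exposure groups need at least one subject",
            class = "gs_undefined_metric")
  if (a + c == 0)
    stop_gs("no outcome events in either group; relative risk undefined",
            class = "gs_undefined_metric")
  r1 <- a / n1; r0 <- c / n0
  rr <- r1 / r0
  z <- stats::qnorm(1 - (1 - conf) / 2)
  continuity <- FALSE
  if (a > 0 && c > 0) {
    se <- sqrt(1 / a - 1 / n1 + 1 / c - 1 / n0)
    lo <- rr * exp(-z * se); hi <- rr * exp(z * se)
  } else {
    continuity <- TRUE
    ac <- a + 0.5; cc <- c + 0.5; n1c <- n1 + 1; n0c <- n0 + 1
    rrc <- (ac / n1c) / (cc / n0c)
    se <- sqrt(1 / ac - 1 / n1c + 1 / cc - 1 / n0c)
    lo <- rrc * exp(-z * se); hi <- rrc * exp(z * se)
  }
  p <- stats::fisher.test(tab)$p.value
  list(rr = rr, lower = lo, upper = hi, p_fisher = p,
       risk_exposed = r1, risk_unexposed = r0,
       infinite = is.infinite(rr), continuity = continuity)
}

#' Test of homogeneity of the relative risk across two strata
#'
#' Assesses whether the exposure-outcome association differs between two
#' strata of a marker (an interaction on the risk-ratio scale): a Wald
#' chi-square comparing the stratum log relative risks with Katz standard
#' errors. A logistic-regression interaction Wald p-value is always computed
#' alongside as a cross-check; the two should broadly agree.
#'
#' @param tab1,tab2 2x2 count matrices (exposure x outcome), one per stratum.
#' @return list with `p` (risk-ratio homogeneity), `p_logistic`,
#'   `statistic`, and the stratum relative risks.
#' @export
mh_interaction <- function(tab1, tab2) {
  for (t in list(tab1, tab2)) {
    t <- as.matrix(t)
    if (any(rowSums(t) == 0))
      stop_gs("each stratum needs subjects in both exposure groups",
              class = "gs_undefined_metric")
  }
  katz <- function(tab) {
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    if (a == 0 || c == 0) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
    n1 <- a + b; n0 <- c + d
    list(log_rr = log((a / n1) / (c / n0)),
         var = 1 / a - 1 / n1 + 1 / c - 1 / n0)
  }
  k1 <- katz(as.matrix(tab1)); k2 <- katz(as.matrix(tab2))
  stat <- (k1$log_rr - k2$log_rr)^2 / (k1$var + k2$var)
  p <- stats::pchisq(stat, 1, lower.tail = FALSE)

  # logistic interaction cross-check on the reconstructed subject table
  expand <- function(tab, stratum) {
    tab <- as.matrix(tab)
    data.frame(
      outcome = rep(c(1, 0, 1, 0), times = c(tab[1, 1], tab[1, 2],
                                             tab[2, 1], tab[2, 2])),
      exposed = rep(c(1, 1, 0, 0), times = c(tab[1, 1], tab[1, 2],
                                             tab[2, 1], tab[2, 2])),
      stratum = stratum)
  }
  dat <- rbind(expand(tab1, 0), expand(tab2, 1))
  fit <- suppressWarnings(stats::glm(outcome ~ exposed * stratum,
                                     family = stats::binomial(), data = dat))
  co <- summary(fit)$coefficients
  p_log <- if ("exposed:stratum" %in% rownames(co))
    co["exposed:stratum", "Pr(>|z|)"] else NA_real_
  list(p = p, statistic = stat, p_logistic = p_log,
       rr1 = exp(k1$log_rr), rr2 = exp(k2$log_rr))
}

# build an exposure x outcome 2x2 with exposed/unexposed rows
risk_table <- function(exposed, outcome, reference = !exposed) {
  keep <- (exposed | reference) & !is.na(outcome) & !is.na(exposed)
  e <- exposed[keep]; o <- outcome[keep]
  matrix(c(sum(e & o), sum(e & !o), sum(!e & o), sum(!e & !o)),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("exposed", "unexposed"), c("event", "no_event")))
}

#' Stratified relative-risk report for screening-by-velocity analyses
#'
#' Builds the perinatal-outcome association table: rows for screen-positive
#' EFW (population standard), screen-positive by customised standard, and
#' screen-positive with normal versus lowest-decile abdominal-circumference
#' growth velocity; columns for each outcome composite. Every cell is a
#' relative risk with Katz 95% CI and Fisher exact p, referent to infants
#' with an EFW at or above the 10th percentile (by the corresponding
#' standard). Subjects with missing growth velocity are excluded from the
#' velocity-stratified rows.
#'
#' @param cls classification data frame from [classify_cohort()].
#' @return data frame in long form (`exposure`, `outcome`, `rr`, `lower`,
#'   `upper`, `p`, `n_exposed`, `events_exposed`, ...), with the per-cell
#'   2x2 ledger in the `tables` attribute.
#' @export
table4_report <- function(cls) {
  need <- c("universal_status", "acgv_bottom_decile", "neonatal_morbidity")
  missing_cols <- setdiff(need, names(cls))
  if (length(missing_cols) > 0)
    stop_gs("classification is missing columns: %s",
            paste(missing_cols, collapse = ", "), class = "gs_missing_input")
  pos <- cls$universal_status == "positive"
  ref <- !pos
  acgv_known <- !is.na(cls$acgv_bottom_decile) & !is.na(cls$acgv)
  exposures <- list(
    efw_lt10_population = list(exp = pos, ref = ref),
    efw_lt10_customised = if ("customised_status" %in% names(cls)) {
      cpos <- cls$customised_status == "positive"
      list(exp = cpos, ref = !cpos)
    },
    efw_lt10_normal_acgv = list(exp = pos & acgv_known & !cls$acgv_bottom_decile,
                                ref = ref),
    efw_lt10_lowest_acgv = list(exp = pos & acgv_known & cls$acgv_bottom_decile,
                                ref = ref)
  )
  exposures <- Filter(Negate(is.null), exposures)
  outcomes <- list(
    neonatal_morbidity = cls$neonatal_morbidity,
    metabolic_acidosis = cls$metabolic_acidosis,
    low_apgar5 = cls$low_apgar5,
    nnu_admission_term = cls$nnu_admission_term,
    sga_plus_morbidity = cls$sga_plus_morbidity,
    severe_adverse = cls$severe_adverse,
    sga_plus_severe = cls$sga_plus_severe
  )
  rows <- list(); tables <- list()
  for (en in names(exposures)) for (on in names(outcomes)) {
    tab <- risk_table(exposures[[en]]$exp, outcomes[[on]],
                      exposures[[en]]$ref)
    rr <- tryCatch(relative_risk(tab), growthscreen_error = function(e) NULL)
    rows[[paste(en, on)]] <- data.frame(
      exposure = en, outcome = on,
      rr = rr$rr %||% NA_real_, lower = rr$lower %||% NA_real_,
      upper = rr$upper %||% NA_real_, p = rr$p_fisher %||% NA_real_,
      n_exposed = sum(tab[1, ]), events_exposed = tab[1, 1],
      n_reference = sum(tab[2, ]), events_reference = tab[2, 1]
    )
    tables[[paste(en, on, sep = ".")]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tables") <- tables
  out
}
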