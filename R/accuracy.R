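#' Paired screening data
#'
#' Joint classification of two screening policies against a binary gold
#' standard, stored as the 2x2x2 table of counts indexed by
#' (test A +/-, test B +/-, disease +/-).
#'
#' @param test_a,test_b logical (or `"positive"`/`"negative"`) screen calls.
#' @param disease logical gold standard.
#' @return object of class `paired_screen_data`: a 2x2x2 integer array with
#'   dimnames `a`, `b`, `d` (level order positive, negative).
#' @export
paired_screen_data <- function(test_a, test_b, disease) {
  as_pos <- function(x) if (is.logical(x)) x else x == "positive"
  a <- as_pos(test_a); b <- as_pos(test_b); d <- as.logical(disease)
  ok <- !(is.na(a) | is.na(b) | is.na(d))
  tab <- table(factor(!a[ok], c(FALSE, TRUE), c("pos", "neg")),
               factor(!b[ok], c(FALSE, TRUE), c("pos", "neg")),
               factor(!d[ok], c(FALSE, TRUE), c("yes", "no")))
  counts <- array(as.integer(tab), dim = c(2, 2, 2),
                  dimnames = list(a = c("pos", "neg"), b = c("pos", "neg"),
                                  d = c("yes", "no")))
  structure(counts, class = "paired_screen_data")
}

#' @rdname paired_screen_data
#' @param counts a 2x2x2 array of counts, first index test A
#'   (positive, negative), second test B, third disease (yes, no).
#' @export
as_paired_screen_data <- function(counts) {
  stopifnot(length(dim(counts)) == 3, all(dim(counts) == 2), all(counts >= 0))
  counts <- array(as.integer(counts), dim = c(2, 2, 2),
                  dimnames = list(a = c("pos", "neg"), b = c("pos", "neg"),
                                  d = c("yes", "no")))
  structure(counts, class = "paired_screen_data")
}

# collapse to one test's 2x2 (tp, fp, fn, tn)
collapse_test <- function(psd, test = c("a", "b")) {
  test <- match.arg(test)
  m <- apply(unclass(psd), c(which(c("a", "b") == test), 3), sum)
  list(tp = m[1, 1], fp = m[1, 2], fn = m[2, 1], tn = m[2, 2])
}

#' Diagnostic summary of a single 2x2 screening table
#'
#' Standard screening metrics with 95% confidence intervals: Wilson score
#' intervals for the proportions, log-method intervals for the likelihood
#' ratios.
#'
#' @param tp,fp,fn,tn cell counts (true/false positives/negatives).
#' @param conf confidence level.
#' @param ci_method `"wilson"` (default; better coverage) or `"wald"`
#'   (simple normal approximation, the method that reproduces many published
#'   screening tables) for the proportion CIs.
#' @return object of class `screen_summary`: a list of metric entries, each
#'   with `est`, `lower`, `upper` (proportions on \[0, 1\]; likelihood ratios
#'   on their natural scale), plus the counts.
#' @export
screen_summary <- function(tp, fp, fn, tn, conf = 0.95,
                           ci_method = c("wilson", "wald")) {
  ci_method <- match.arg(ci_method)
  prop_ci <- if (ci_method == "wilson") wilson_ci else wald_ci
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  nd <- tp + fn; nh <- fp + tn
  if (nd == 0) stop_gs("sensitivity undefined: zero diseased subjects",
                       class = "gs_undefined_metric")
  if (nh == 0) stop_gs("specificity undefined: zero non-diseased subjects",
                       class = "gs_undefined_metric")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lr_ci <- function(est, var_log) {
    if (!is.finite(est) || est == 0 || !is.finite(var_log))
      return(list(est = est, lower = NA_real_, upper = NA_real_))
    list(est = est, lower = est * exp(-z * sqrt(var_log)),
         upper = est * exp(z * sqrt(var_log)))
  }
  sens <- tp / nd; spec <- tn / nh
  out <- list(
    sensitivity = prop_ci(tp, nd, conf),
    specificity = prop_ci(tn, nh, conf),
    ppv = if (tp + fp > 0) prop_ci(tp, tp + fp, conf) else
      list(est = NA_real_, lower = NA_real_, upper = NA_real_),
    npv = if (tn + fn > 0) prop_ci(tn, tn + fn, conf) else
      list(est = NA_real_, lower = NA_real_, upper = NA_real_),
    fpr = prop_ci(fp, nh, conf),
    fnr = prop_ci(fn, nd, conf),
    lr_pos = lr_ci(sens / (1 - spec), 1 / tp - 1 / nd + 1 / fp - 1 / nh),
    lr_neg = lr_ci((1 - sens) / spec, 1 / fn - 1 / nd + 1 / tn - 1 / nh),
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn)
  )
  structure(out, class = "screen_summary")
}

# Exact (binomial) or continuity-corrected chi-square McNemar p-value on a
# discordant pair count; the switch at 25 discordant pairs is standard
# practice.
mcnemar_p <- function(b, c, exact_below = 25) {
  n <- b + c
  if (n == 0) return(1)
  if (n < exact_below) return(stats::binom.test(b, n, 0.5)$p.value)
  stat <- (abs(b - c) - 1)^2 / n
  stats::pchisq(stat, 1, lower.tail = FALSE)
}

# delta-method variance of log(pB/pA) for paired proportions with joint
# success probability p11, sample size n
paired_log_ratio_var <- function(pA, pB, p11, n) {
  ((1 - pA) / pA + (1 - pB) / pB - 2 * (p11 - pA * pB) / (pA * pB)) / n
}

#' Relative sensitivity of paired screening tests
#'
#' Ratio of the two tests' sensitivities on the same diseased subjects
#' (test B relative to test A), with a log-delta-method CI that accounts for
#' the pairing, and a McNemar test on the discordant diseased pairs (exact
#' binomial below 25 discordant pairs, otherwise continuity-corrected
#' chi-square).
#'
#' @param psd a [paired_screen_data()] object.
#' @param conf confidence level.
#' @return list with `ratio`, `lower`, `upper`, `p_mcnemar`, the two
#'   sensitivities and the discordant counts.
#' @export
relative_sensitivity <- function(psd, conf = 0.95) {
  stopifnot(inherits(psd, "paired_screen_data"))
  dz <- unclass(psd)[, , "yes"]
  nd <- sum(dz)
  if (nd == 0) stop_gs("no diseased subjects; relative sensitivity undefined",
                       class = "gs_undefined_metric")
  n11 <- dz["pos", "pos"]; n10 <- dz["pos", "neg"]; n01 <- dz["neg", "pos"]
  sens_a <- (n11 + n10) / nd
  sens_b <- (n11 + n01) / nd
  ratio <- sens_b / sens_a
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (sens_a > 0 && sens_b > 0) {
    v <- paired_log_ratio_var(sens_a, sens_b, n11 / nd, nd)
    lo <- ratio * exp(-z * sqrt(max(v, 0)))
    hi <- ratio * exp(z * sqrt(max(v, 0)))
  } else lo <- hi <- NA_real_
  list(ratio = ratio, lower = lo, upper = hi,
       p_mcnemar = mcnemar_p(n10, n01),
       sens_a = sens_a, sens_b = sens_b, discordant = c(a_only = n10,
                                                        b_only = n01))
}

# multinomial bootstrap over the 8 joint cells; statfn maps a 2x2x2 count
# array to a scalar
boot_paired <- function(psd, statfn, B, seed) {
  counts <- as.vector(unclass(psd))
  n <- sum(counts)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draws <- stats::rmultinom(B, n, counts / n)
  apply(draws, 2, function(v) statfn(array(v, dim = c(2, 2, 2))))
}

predictive_components <- function(psd, which) {
  x <- unclass(psd)
  if (which == "ppv") {
    # records: positive calls; outcome = diseased
    list(nA = sum(x[1, , ]), nB = sum(x[, 1, ]),
         dA = sum(x[1, , 1]), dB = sum(x[, 1, 1]),
         both = x[1, 1, ], outcome_yes = 1L)
  } else {
    list(nA = sum(x[2, , ]), nB = sum(x[, 2, ]),
         dA = sum(x[2, , 2]), dB = sum(x[, 2, 2]),
         both = x[2, 2, ], outcome_yes = 2L)
  }
}

pv_estimates <- function(counts, which) {
  x <- counts
  if (which == "ppv") c(a = sum(x[1, , 1]) / sum(x[1, , ]),
                        b = sum(x[, 1, 1]) / sum(x[, 1, ]))
  else c(a = sum(x[2, , 2]) / sum(x[2, , ]),
         b = sum(x[, 2, 2]) / sum(x[, 2, ]))
}

#' Generalised score test comparing predictive values of paired tests
#'
#' Compares the positive (or negative) predictive values of two screening
#' tests applied to the same subjects. Each subject contributes one record
#' per test that called them positive (for PPV; negative for NPV); the score
#' for the test contrast is evaluated under the pooled null predictive value
#' with a cluster-robust (empirical) variance, so subjects positive on both
#' tests are handled correctly. A paired multinomial bootstrap p-value is
#' computed alongside as a cross-check.
#'
#' @param psd a [paired_screen_data()] object.
#' @param which `"ppv"` or `"npv"`.
#' @param B bootstrap replicates (0 to skip).
#' @param seed seed for the bootstrap.
#' @return list with `statistic` (chi-square, 1 df), `p`, the two predictive
#'   values, and `p_boot`.
#' @export
predictive_value_test <- function(psd, which = c("ppv", "npv"), B = 2000,
                                  seed = 1) {
  which <- match.arg(which)
  stopifnot(inherits(psd, "paired_screen_data"))
  x <- unclass(psd)
  comp <- predictive_components(psd, which)
  if (comp$nA == 0 || comp$nB == 0)
    stop_gs("one test made no %s calls; the score test is degenerate -- use the paired bootstrap on a richer statistic instead",
            if (which == "ppv") "positive" else "negative",
            class = "gs_degenerate_error")
  N <- comp$nA + comp$nB
  xbar <- comp$nB / N
  pbar <- (comp$dA + comp$dB) / N

  # per-cell score contributions; cells are (a, b, d)
  idx <- expand.grid(a = 1:2, b = 1:2, d = 1:2)
  U <- 0; V <- 0
  for (r in seq_len(nrow(idx))) {
    a <- idx$a[r]; b <- idx$b[r]; dd <- idx$d[r]
    cnt <- x[a, b, dd]
    if (cnt == 0) next
    dval <- as.numeric(dd == comp$outcome_yes)
    contrib <- 0
    in_a <- (which == "ppv" && a == 1) || (which == "npv" && a == 2)
    in_b <- (which == "ppv" && b == 1) || (which == "npv" && b == 2)
    if (in_a) contrib <- contrib + (0 - xbar) * (dval - pbar)
    if (in_b) contrib <- contrib + (1 - xbar) * (dval - pbar)
    U <- U + cnt * contrib
    V <- V + cnt * contrib^2
  }
  stat <- if (V > 0) U^2 / V else 0
  p <- if (V > 0) stats::pchisq(stat, 1, lower.tail = FALSE) else 1
  est <- pv_estimates(x, which)
  p_boot <- NA_real_
  if (B > 0) {
    diffs <- boot_paired(psd, function(cnt) {
      e <- pv_estimates(cnt, which)
      e["b"] - e["a"]
    }, B, seed)
    diffs <- diffs[is.finite(diffs)]
    p_boot <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  }
  list(statistic = stat, p = p, pv_a = unname(est["a"]), pv_b = unname(est["b"]),
       p_boot = p_boot)
}

# paired log-ratio contrast within a disease stratum; event = positive call
# (or negative call for LR-)
stratum_log_ratio <- function(strat, event_row = 1) {
  n <- sum(strat)
  pA <- sum(strat[event_row, ]) / n
  pB <- sum(strat[, event_row]) / n
  p11 <- strat[event_row, event_row] / n
  list(log_ratio = log(pB / pA),
       var = paired_log_ratio_var(pA, pB, p11, n), pA = pA, pB = pB)
}

#' Regression-model-based comparison of paired likelihood ratios
#'
#' The log positive likelihood ratio is `log P(T+|D+) - log P(T+|D-)`; the
#' between-test contrast is therefore the difference between the paired log
#' sensitivity ratio (diseased stratum) and the paired log false-positive-
#' rate ratio (non-diseased stratum). Both components use paired
#' delta-method variances and the strata are independent, giving a Wald test
#' equivalent to the log-linear model contrast. A paired multinomial
#' bootstrap p-value is computed alongside.
#'
#' @param psd a [paired_screen_data()] object.
#' @param which `"pos"` or `"neg"` likelihood ratio.
#' @param B bootstrap replicates (0 to skip).
#' @param seed bootstrap seed.
#' @return list with `log_ratio` (log LR_B - log LR_A), `z`, `p`, the two
#'   likelihood ratios, and `p_boot`.
#' @export
likelihood_ratio_test <- function(psd, which = c("pos", "neg"), B = 2000,
                                  seed = 1) {
  which <- match.arg(which)
  stopifnot(inherits(psd, "paired_screen_data"))
  x <- unclass(psd)
  event_row <- if (which == "pos") 1 else 2
  sd1 <- stratum_log_ratio(x[, , 1], event_row)  # diseased stratum
  sd0 <- stratum_log_ratio(x[, , 2], event_row)  # non-diseased stratum
  theta <- sd1$log_ratio - sd0$log_ratio
  v <- sd1$var + sd0$var
  lr <- function(cnt) {
    s1 <- sum(cnt[event_row, , 1]) / sum(cnt[, , 1])
    s1b <- sum(cnt[, event_row, 1]) / sum(cnt[, , 1])
    f0 <- sum(cnt[event_row, , 2]) / sum(cnt[, , 2])
    f0b <- sum(cnt[, event_row, 2]) / sum(cnt[, , 2])
    c(a = s1 / f0, b = s1b / f0b)
  }
  est <- lr(x)
  if (!is.finite(theta) || is.na(v)) {
    z <- NA_real_; p <- NA_real_
  } else if (v <= 0) {
    z <- 0; p <- 1
  } else {
    z <- theta / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  p_boot <- NA_real_
  if (B > 0) {
    diffs <- boot_paired(psd, function(cnt) {
      e <- lr(cnt)
      log(e["b"]) - log(e["a"])
    }, B, seed)
    diffs <- diffs[is.finite(diffs)]
    p_boot <- min(1, 2 * min(mean(diffs <= 0), mean(diffs >= 0)))
  }
  list(log_ratio = theta, z = z, p = p, lr_a = unname(est["a"]),
       lr_b = unname(est["b"]), p_boot = p_boot)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC via the Mann-Whitney identity (higher score indicates disease), CI by
#' DeLong's method.
#'
#' @param score continuous per-subject score.
#' @param disease logical disease status.
#' @param conf confidence level.
#' @return list with `auc`, `lower`, `upper`.
#' @export
roc_auc <- function(score, disease, conf = 0.95) {
  disease <- as.logical(disease)
  if (length(unique(disease[!is.na(disease)])) < 2)
    stop_gs("need both diseased and non-diseased subjects for ROC analysis",
            class = "gs_undefined_metric")
  r <- pROC::roc(response = disease, predictor = score,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- pROC::ci.auc(r, conf.level = conf, method = "delong")
  list(auc = as.numeric(pROC::auc(r)), lower = ci[1], upper = ci[3])
}

#' Diagnostic-effectiveness report for paired screening policies
#'
#' Formats the paired comparison the way screening papers print it: one row
#' per metric, percentages rounded half-up to integers and likelihood ratios
#' to one decimal, 95% CIs in brackets, plus the relative sensitivity row.
#'
#' @param psd a [paired_screen_data()] object (test A = selective,
#'   test B = universal by convention).
#' @param labels column labels for the two tests.
#' @return data frame with formatted columns, carrying the full-precision
#'   summaries in the `summaries` attribute.
#' @export
accuracy_report <- function(psd, labels = c("selective", "universal")) {
  ca <- collapse_test(psd, "a"); cb <- collapse_test(psd, "b")
  sa <- screen_summary(ca$tp, ca$fp, ca$fn, ca$tn)
  sb <- screen_summary(cb$tp, cb$fp, cb$fn, cb$tn)
  rs <- relative_sensitivity(psd)
  fmt_pct <- function(m) sprintf("%d%% (%d-%d)", round_half_up(100 * m$est),
                                 round_half_up(100 * m$lower),
                                 round_half_up(100 * m$upper))
  fmt_lr <- function(m) sprintf("%.1f (%.1f-%.1f)", round_half_up(m$est, 1),
                                round_half_up(m$lower, 1),
                                round_half_up(m$upper, 1))
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "fpr", "fnr")
  out <- data.frame(
    metric = c(metrics, "lr_pos", "lr_neg", "relative_sensitivity"),
    a = c(vapply(metrics, function(m) fmt_pct(sa[[m]]), ""),
          fmt_lr(sa$lr_pos), fmt_lr(sa$lr_neg), "1.0 (reference)"),
    b = c(vapply(metrics, function(m) fmt_pct(sb[[m]]), ""),
          fmt_lr(sb$lr_pos), fmt_lr(sb$lr_neg),
          sprintf("%.1f (%.1f-%.1f)", round_half_up(rs$ratio, 1),
                  round_half_up(rs$lower, 1), round_half_up(rs$upper, 1)))
  )
  names(out) <- c("metric", labels)
  attr(out, "summaries") <- list(a = sa, b = sb, relative_sensitivity = rs)
  out
}
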