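# Toy internally consistent standards so tests never depend on the accuracy
# of the shipped coefficient transcriptions.

toy_efw_standard <- function(cv = 0.1) {
  as_growth_standard(
    kind = "efw_for_ga",
    location = function(ga, sex = NULL) 100 * ga,
    scale = function(ga, sex = NULL) cv * 100 * ga,
    ga_range = c(12, 43), name = "toy_efw"
  )
}

# linear-in-GA birthweight table with a constant sex offset, via the same
# CSV loader the registry uses
toy_bw_standard <- function() {
  tab <- expand.grid(ga_weeks = 24:43, sex = c("M", "F"),
                     KEEP.OUT.ATTRS = FALSE)
  tab$mean_g <- 200 * (tab$ga_weeks - 20) + ifelse(tab$sex == "M", 100, 0)
  tab$sd_g <- 400
  path <- tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  fg_standard(path)
}

# one subject's scan table
make_scans <- function(ga, policy, hc = 300, ac = 280, fl = 60) {
  data.frame(subject_id = 1, scan_ga_weeks = ga, scan_policy = policy,
             hc_mm = hc, ac_mm = ac, fl_mm = fl)
}

# minimal outcomes row with benign defaults, overridable per field
make_outcome <- function(...) {
  base <- data.frame(subject_id = 1, ga_delivery_weeks = 40,
                     birthweight_g = 3500, sex = "M", apgar5 = 9,
                     cord_ph = 7.3, cord_base_deficit = 4,
                     nnu_admission = FALSE, nnu_admit_hours = NA_real_,
                     nnu_discharge_hours = NA_real_, stillbirth = FALSE,
                     neonatal_death = FALSE, hie = FALSE, inotropes = FALSE,
                     mechanical_ventilation = FALSE)
  utils::modifyList(base, list(...))
}

small_cohort <- function(n = 400, seed = 42, ...) {
  generate_cohort(cohort_params(n_subjects = n, seed = seed, ...))
}

# exhaustive two-sided Fisher p by hypergeometric enumeration (oracle)
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
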