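#' Growth-standard registry
#'
#' All percentile computations run against pluggable reference standards:
#' JSON/CSV files giving, for each gestational age (and sex where relevant),
#' a location (median/mean) and a scale (SD) on a working scale (natural or
#' log). Shipped standards:
#'
#' * `"hadlock1991_efw_ga"` — sonographic weight-for-GA standard with median
#'   `exp(0.578 + 0.332 ga - 0.00354 ga^2)` g and SD equal to 12.7% of the
#'   median (kind `efw_for_ga`).
#' * `"birthweight_uk_synthetic"` — a synthetic smooth birthweight-for-GA-and-
#'   sex table (kind `birthweight_for_ga_sex`); a stand-in with the shape of a
#'   national reference, clearly labelled synthetic.
#'
#' @param name registry name or a path to a standard file.
#' @return an object of class `growth_standard` with elements `name`, `kind`,
#'   `working_scale`, `ga_range`, and vectorised functions
#'   `location(ga, sex)` and `scale(ga, sex)`.
#' @export
fg_standard <- function(name) {
  if (file.exists(name)) path <- name
  else {
    dir <- system.file("extdata", "standards", package = "growthscreen")
    cands <- file.path(dir, paste0(name, c(".json", ".csv")))
    path <- cands[file.exists(cands)][1]
    if (is.na(path))
      stop_gs("unknown growth standard '%s'", name, class = "gs_config_error")
  }
  if (grepl("\\.json$", path)) {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (identical(spec$kind, "efw_for_ga")) return(standard_from_logquad(spec))
    stop_gs("unsupported standard kind in '%s'", path, class = "gs_config_error")
  }
  standard_from_table(utils::read.csv(path), name = basename(path))
}

standard_from_logquad <- function(spec) {
  co <- spec$median_log_coefficients
  loc <- function(ga, sex = NULL) exp(co$c0 + co$c1 * ga + co$c2 * ga^2)
  cv <- spec$sd_fraction_of_median
  structure(list(
    name = spec$name, kind = spec$kind, working_scale = spec$working_scale,
    ga_range = as.numeric(spec$ga_range), citation = spec$citation,
    location = loc,
    scale = function(ga, sex = NULL) cv * loc(ga)
  ), class = "growth_standard")
}

standard_from_table <- function(tab, name = "table") {
  stopifnot(all(c("ga_weeks", "sex", "mean_g", "sd_g") %in% names(tab)))
  split_tab <- split(tab, tab$sex)
  rng <- range(tab$ga_weeks)
  interp <- function(col) {
    function(ga, sex) {
      stopifnot(length(sex) %in% c(1L, length(ga)))
      sex <- rep_len(as.character(sex), length(ga))
      out <- numeric(length(ga))
      for (s in unique(sex)) {
        st <- split_tab[[s]]
        if (is.null(st))
          stop_gs("sex '%s' not covered by standard '%s'", s, name,
                  class = "gs_range_error")
        i <- sex == s
        out[i] <- stats::approx(st$ga_weeks, st[[col]], xout = ga[i],
                                rule = 1)$y
      }
      out
    }
  }
  structure(list(
    name = name, kind = "birthweight_for_ga_sex", working_scale = "natural",
    ga_range = rng, citation = attr(tab, "citation"),
    location = interp("mean_g"), scale = interp("sd_g")
  ), class = "growth_standard")
}

#' Construct a growth standard from location/scale functions
#'
#' Mainly used to define small internally consistent standards in tests and
#' simulations without touching the registry files.
#'
#' @param kind one of `"efw_for_ga"`, `"measure_for_ga"`,
#'   `"birthweight_for_ga_sex"`.
#' @param location,scale vectorised functions of `(ga, sex)`.
#' @param ga_range numeric length-2 GA domain in weeks.
#' @param working_scale `"natural"` or `"log"`.
#' @param name label.
#' @return a `growth_standard` object.
#' @export
as_growth_standard <- function(kind, location, scale, ga_range,
                               working_scale = "natural", name = "custom") {
  structure(list(name = name, kind = kind, working_scale = working_scale,
                 ga_range = as.numeric(ga_range), citation = NULL,
                 location = location, scale = scale),
            class = "growth_standard")
}

check_ga_domain <- function(ga, std) {
  bad <- ga < std$ga_range[1] | ga > std$ga_range[2] | !is.finite(ga)
  if (any(bad))
    stop_gs("gestational age %s outside standard '%s' domain [%g, %g] weeks",
            paste(ga[bad][1]), std$name, std$ga_range[1], std$ga_range[2],
            class = "gs_range_error")
}

load_efw_equation <- function(variant) {
  path <- system.file("extdata", "standards", "efw_equations.json",
                      package = "growthscreen")
  eqs <- jsonlite::read_json(path, simplifyVector = TRUE)$equations
  eq <- eqs[[variant]]
  if (is.null(eq))
    stop_gs("unknown EFW equation variant '%s' (have: %s)", variant,
            paste(names(eqs), collapse = ", "), class = "gs_config_error")
  eq
}

#' Hadlock estimated fetal weight
#'
#' Evaluates the Hadlock log10 regression of fetal weight on biometry. The
#' default three-parameter model uses head circumference (HC), abdominal
#' circumference (AC) and femur length (FL); the four-parameter variant adds
#' biparietal diameter (BPD). Inputs are centimetres, output grams.
#'
#' @param hc_cm,ac_cm,fl_cm,bpd_cm biometry in cm (vectors recycled to common
#'   length). `bpd_cm` is only required by the `"bpdhcacfl"` variant.
#' @param variant `"hcacfl"` (default) or `"bpdhcacfl"`.
#' @return estimated fetal weight in grams.
#' @export
#' @examples
#' hadlock_efw(hc_cm = 30, ac_cm = 26, fl_cm = 5.5)
hadlock_efw <- function(hc_cm, ac_cm, fl_cm, bpd_cm = NULL,
                        variant = c("hcacfl", "bpdhcacfl")) {
  variant <- match.arg(variant)
  eq <- load_efw_equation(variant)
  need <- list(hc_cm = hc_cm, ac_cm = ac_cm, fl_cm = fl_cm)
  if (variant == "bpdhcacfl") {
    if (is.null(bpd_cm))
      stop_gs("variant 'bpdhcacfl' requires bpd_cm", class = "gs_missing_input")
    need$bpd_cm <- bpd_cm
  }
  for (nm in names(need)) {
    v <- need[[nm]]
    if (is.null(v) || anyNA(v))
      stop_gs("missing required measure '%s'", nm, class = "gs_missing_input")
    if (any(v <= 0))
      stop_gs("nonpositive value in measure '%s'", nm, class = "gs_domain_error")
  }
  l10 <- eq$intercept + eq$ac_fl * ac_cm * fl_cm + eq$hc * hc_cm +
    eq$ac * ac_cm + eq$fl * fl_cm
  if (variant == "bpdhcacfl") l10 <- l10 + eq$bpd_ac * bpd_cm * ac_cm
  10^l10
}

percentile_from_standard <- function(value, ga, std, sex = NULL) {
  loc <- std$location(ga, sex)
  sc <- std$scale(ga, sex)
  z <- if (identical(std$working_scale, "log")) {
    (log(value) - log(loc)) / sc
  } else {
    (value - loc) / sc
  }
  100 * stats::pnorm(z)
}

#' EFW percentile for gestational age
#'
#' Converts an estimated fetal weight into a percentile under a weight-for-GA
#' standard: `100 * pnorm((t(efw) - t(location(ga))) / scale(ga))` with `t`
#' the standard's working-scale transform.
#'
#' @param efw_g estimated fetal weight in grams.
#' @param ga_weeks decimal gestational age in weeks.
#' @param standard a `growth_standard` of kind `efw_for_ga`.
#' @return percentile in (0, 100).
#' @export
efw_percentile <- function(efw_g, ga_weeks,
                           standard = fg_standard("hadlock1991_efw_ga")) {
  stopifnot(inherits(standard, "growth_standard"))
  if (!identical(standard$kind, "efw_for_ga"))
    stop_gs("standard '%s' has kind '%s', need 'efw_for_ga'", standard$name,
            standard$kind, class = "gs_config_error")
  check_ga_domain(ga_weeks, standard)
  percentile_from_standard(efw_g, ga_weeks, standard)
}

#' Birthweight percentile for gestational age and sex
#'
#' @param bw_g birthweight in grams.
#' @param ga_weeks decimal gestational age at delivery.
#' @param sex `"M"` or `"F"` (vector recycled).
#' @param standard a `growth_standard` of kind `birthweight_for_ga_sex`;
#'   gestational age is interpolated linearly between tabulated weeks.
#' @return percentile in (0, 100).
#' @export
birthweight_percentile <- function(bw_g, ga_weeks, sex,
    standard = fg_standard("birthweight_uk_synthetic")) {
  stopifnot(inherits(standard, "growth_standard"))
  if (!identical(standard$kind, "birthweight_for_ga_sex"))
    stop_gs("standard '%s' has kind '%s', need 'birthweight_for_ga_sex'",
            standard$name, standard$kind, class = "gs_config_error")
  check_ga_domain(ga_weeks, standard)
  percentile_from_standard(bw_g, ga_weeks, standard, sex = sex)
}

#' Default customisation coefficient set
#'
#' Loads the shipped simplified customisation model (term optimal weight with
#' linear height/weight/ethnicity/smoking offsets). These are illustrative
#' surrogate coefficients, not a proprietary customisation model.
#'
#' @param path optional path to an alternative coefficient JSON file.
#' @return a named list of coefficients.
#' @export
fg_customisation <- function(path = NULL) {
  path <- path %||% system.file("extdata", "standards",
                                "customisation_surrogate.json",
                                package = "growthscreen")
  if (!file.exists(path))
    stop_gs("customisation coefficient file '%s' not found", path,
            class = "gs_config_error")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Customised EFW percentile
#'
#' Scales a maternal-characteristic-adjusted term optimal weight along the
#' fetal weight-for-GA proportionality curve and evaluates the percentile
#' under a proportional-SD normal model, mirroring customised-centile
#' methodology with a simplified, pluggable coefficient set.
#'
#' @param efw_g estimated fetal weight in grams.
#' @param ga_weeks decimal gestational age in weeks.
#' @param height_cm,weight_kg,ethnicity,smoker maternal characteristics;
#'   `ethnicity` must be one of the coefficient set's ethnicity codes.
#' @param coefs coefficient list from [fg_customisation()].
#' @param standard weight-for-GA standard supplying the proportionality curve.
#' @return percentile in (0, 100).
#' @export
customised_percentile <- function(efw_g, ga_weeks, height_cm, weight_kg,
                                  ethnicity = "white", smoker = FALSE,
                                  coefs = fg_customisation(),
                                  standard = fg_standard("hadlock1991_efw_ga")) {
  check_ga_domain(ga_weeks, standard)
  eth <- unname(unlist(coefs$ethnicity_g)[as.character(ethnicity)])
  if (anyNA(eth))
    stop_gs("ethnicity code(s) %s not in coefficient set",
            paste(unique(ethnicity[is.na(eth)]), collapse = ", "),
            class = "gs_config_error")
  tow <- coefs$base_term_weight_g +
    coefs$height_g_per_cm * (height_cm - coefs$reference_height_cm) +
    coefs$weight_g_per_kg * (weight_kg - coefs$reference_weight_kg) +
    eth + ifelse(smoker, coefs$smoker_g, 0)
  prop <- standard$location(ga_weeks) / standard$location(coefs$term_ga_weeks)
  expected <- tow * prop
  100 * stats::pnorm((efw_g - expected) / (coefs$cv * expected))
}
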