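#' Synthetic Gompertz life tables
#'
#' Generates a life table from the Gompertz mortality law with hazard
#' `h(x) = a * exp(b * x)`, giving annual death probabilities
#' `q(x) = 1 - exp(-(a / b) * exp(b * x) * (exp(b) - 1))`. This is a
#' synthetic stand-in for a national period life table: the default
#' calibration (see [calibrate_gompertz()]) targets a remaining life
#' expectancy of about 20 years at age 63, typical of a southern-European
#' population around that age. Any real two-column life-table CSV can be
#' supplied instead via [read_lifetable()].
#'
#' @param a Baseline hazard at age 0 (per year), `a >= 0`.
#' @param b Log-hazard slope (per year of age), `b > 0`.
#' @param age_min,age_max Integer age range covered by the table.
#' @return A `lifetable` covering `age_min:age_max`. For `a > 0`, `q`
#'   is strictly increasing in age; for `a = 0` all `q` are zero.
#' @export
make_gompertz_lifetable <- function(a, b, age_min = 0L, age_max = 110L) {
  if (!is.finite(a) || a < 0) stop("`a` must be >= 0", call. = FALSE)
  if (!is.finite(b) || b <= 0) stop("`b` must be > 0", call. = FALSE)
  if (age_min > age_max) stop("age_min > age_max", call. = FALSE)
  ages <- seq.int(age_min, age_max)
  q <- 1 - exp(-(a / b) * exp(b * ages) * (exp(b) - 1))
  make_lifetable(ages, pmin(q, 1))
}

#' Calibrate the Gompertz baseline hazard to a target life expectancy
#'
#' Fixes the slope `b` and solves for the baseline hazard `a` such that
#' the remaining life expectancy at `at_age` (computed by survival-curve
#' summation over the generated table) equals `target_le`. The default
#' slope of 0.09/year is a typical adult value for high-income
#' populations.
#'
#' @param target_le Target remaining life expectancy in years.
#' @param at_age Age at which the target applies.
#' @param b Fixed log-hazard slope.
#' @return Named list with components `a` and `b`.
#' @export
calibrate_gompertz <- function(target_le = 20, at_age = 63, b = 0.09) {
  f <- function(log_a) {
    lt <- make_gompertz_lifetable(exp(log_a), b, 0L, 120L)
    life_expectancy(lt, at_age) - target_le
  }
  root <- stats::uniroot(f, c(-25, -1), tol = 1e-12)$root
  list(a = exp(root), b = b)
}

#' Default synthetic background-mortality table
#'
#' The Gompertz table used throughout the package when no national life
#' table is supplied: slope 0.09/year, baseline hazard calibrated so the
#' remaining life expectancy at age 63 is 20 years.
#'
#' @return A `lifetable` covering ages 0-120.
#' @export
default_lifetable <- function() {
  gp <- calibrate_gompertz()
  make_gompertz_lifetable(gp$a, gp$b, 0L, 120L)
}

#' Baseline model parameter set
#'
#' The published base case, built in code: a 100-patient clinically N0
#' cohort aged 63, nodal prevalence 30%, metastatic prevalence 10%;
#' sensitivity/specificity of 67.6%/67.0% (CT), 70.6%/62.6% (MRI) and
#' 83.3%/84.8% (PET/CT); EOPYY-tariff exam costs of EUR 383/592/580;
#' dissection and resection costs; EUR 400/year follow-up and EUR
#' 32,269/year recurrence and metastatic-disease costs; annual
#' recurrence probabilities 12.8% (TN, FP, TP) and 15.7% (FN); 17%
#' annual disease-specific death probability for N+ and metastatic
#' patients; 3% discounting over a 10-year horizon with half-cycle
#' correction. The uncertainty table carries the published
#' means/bounds/distribution families verbatim, including the rows whose
#' printed bounds are inconsistent (normalized downstream by
#' [normalize_interval()]); the follow-up cost row is flagged `clerical`
#' because its printed bounds were copied from the adjacent row.
#'
#' Identical to the packaged fixture file
#' `extdata/baseline_parameters.yaml`.
#'
#' @return An `nstage_params` object.
#' @export
baseline_parameters <- function() {
  unc <- function(id, family, mean, lower, upper, clerical = FALSE) {
    data.frame(parameter_id = id, family = family, mean = mean,
               lower = lower, upper = upper, clerical = clerical,
               stringsAsFactors = FALSE)
  }
  uncertainty <- rbind(
    unc("prevalence_nodal",      "beta",      0.300, 0.300, 0.270),
    unc("prevalence_metastatic", "beta",      0.100, 0.100, 0.090),
    unc("discount_rate",         "uniform",   0.030, 0.020, 0.040),
    unc("sensitivity_CT",        "beta",      0.676, 0.608, 0.744),
    unc("specificity_CT",        "beta",      0.670, 0.574, 0.767),
    unc("sensitivity_MRI",       "beta",      0.706, 0.635, 0.777),
    unc("specificity_MRI",       "beta",      0.626, 0.527, 0.726),
    unc("sensitivity_PETCT",     "beta",      0.833, 0.750, 0.916),
    unc("specificity_PETCT",     "beta",      0.848, 0.763, 0.933),
    unc("exam_CT",               "lognormal", 383,   344,   421),
    unc("exam_MRI",              "lognormal", 592,   532,   651),
    unc("exam_PETCT",            "lognormal", 580,   522,   638),
    unc("elective_dissection",   "lognormal", 4271,  3844,  4698),
    unc("radical_dissection",    "lognormal", 4271,  3844,  4698),
    unc("resection_nodal_chemo", "lognormal", 24604, 22144, 27064),
    unc("followup_annual",       "lognormal", 400,   29042, 35496, TRUE),
    unc("metastatic_annual",     "lognormal", 32269, 29042, 35496),
    unc("recurrence_annual",     "lognormal", 32269, 29042, 35496),
    unc("p_recurrence_tn",       "beta",      0.128, 0.128, 0.115),
    unc("p_recurrence_fp",       "beta",      0.128, 0.128, 0.115),
    unc("p_recurrence_tp",       "beta",      0.128, 0.128, 0.115),
    unc("p_recurrence_fn",       "beta",      0.157, 0.157, 0.141),
    unc("p_death_nplus",         "beta",      0.170, 0.170, 0.153),
    unc("p_death_metastatic",    "beta",      0.170, 0.128, 0.115)
  )
  load_parameter_set(list(
    epidemiology = list(cohort_size = 100, initial_age = 63,
                        prevalence_nodal = 0.30,
                        prevalence_metastatic = 0.10),
    accuracy = list(
      CT = list(sensitivity = 0.676, specificity = 0.670),
      MRI = list(sensitivity = 0.706, specificity = 0.626),
      PETCT = list(sensitivity = 0.833, specificity = 0.848)
    ),
    costs = list(
      exam = list(CT = 383, MRI = 592, PETCT = 580),
      elective_dissection = 4271,
      radical_dissection = 4271,
      resection_nodal_chemo = 24604,
      followup_annual = 400,
      recurrence_annual = 32269,
      metastatic_annual = 32269
    ),
    transitions = list(
      p_recurrence_tn = 0.128, p_recurrence_fp = 0.128,
      p_recurrence_tp = 0.128, p_recurrence_fn = 0.157,
      p_death_nplus = 0.17, p_death_metastatic = 0.17
    ),
    economics = list(discount_rate = 0.03, horizon_years = 10,
                     cycle_length_years = 1, half_cycle_correction = TRUE),
    uncertainty = uncertainty
  ))
}

#' Random valid parameter scenario for property-based testing
#'
#' Draws a structurally valid parameter set (all probabilities strictly
#' inside (0, 1), prevalences summing below 1, positive costs) from wide
#' uniform ranges. Seeded and reproducible; the uncertainty table is
#' copied from the baseline so sampling machinery can be exercised on
#' random scenarios too.
#'
#' @param seed Integer seed.
#' @return An `nstage_params` object passing [validate_parameter_set()].
#' @export
random_scenario <- function(seed) {
  set.seed(seed)
  r <- function(lo, hi) stats::runif(1, lo, hi)
  prev_n <- r(0.05, 0.6)
  prev_m <- r(0.01, min(0.3, 0.95 - prev_n))
  acc <- function() list(sensitivity = r(0.5, 0.99),
                         specificity = r(0.5, 0.99))
  params <- list(
    epidemiology = list(cohort_size = r(10, 1000), initial_age = r(40, 80),
                        prevalence_nodal = prev_n,
                        prevalence_metastatic = prev_m),
    accuracy = list(CT = acc(), MRI = acc(), PETCT = acc()),
    costs = list(
      exam = list(CT = r(100, 1000), MRI = r(100, 1000),
                  PETCT = r(100, 1000)),
      elective_dissection = r(1000, 10000),
      radical_dissection = r(1000, 10000),
      resection_nodal_chemo = r(5000, 50000),
      followup_annual = r(100, 1000),
      recurrence_annual = r(5000, 50000),
      metastatic_annual = r(5000, 50000)
    ),
    transitions = list(
      p_recurrence_tn = r(0.01, 0.4), p_recurrence_fp = r(0.01, 0.4),
      p_recurrence_tp = r(0.01, 0.4), p_recurrence_fn = r(0.01, 0.4),
      p_death_nplus = r(0.01, 0.5), p_death_metastatic = r(0.01, 0.5)
    ),
    economics = list(discount_rate = r(0, 0.08),
                     horizon_years = sample(1:25, 1),
                     cycle_length_years = 1,
                     half_cycle_correction = TRUE)
  )
  params$uncertainty <- baseline_parameters()$uncertainty
  load_parameter_set(params)
}
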