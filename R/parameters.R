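#' Model configuration
#'
#' Structural settings of the cohort model: discounting, age range, cycle
#' length, cohort size, fracture endpoint, willingness-to-pay thresholds and
#' time-horizon / risk-scale switches. These are never sampled in probabilistic
#' sensitivity analysis.
#'
#' @param discount_rate Annual discount rate applied to both costs and QALYs
#'   (proportion, `0 <= r < 1`). Default 0.035.
#' @param start_age Age (years) at model entry. Default 40.
#' @param end_age Age (years) at which follow-up stops. Default 100.
#' @param cycle_length Cycle length in years; the model is annual, fixed at 1.
#' @param cohort_size Number of persons entering the model. Default 1000.
#' @param fracture_type `"MOF"` (major osteoporotic fracture) or `"HF"`
#'   (hip fracture); the model is run separately for each endpoint.
#' @param thresholds Strictly increasing, strictly positive willingness-to-pay
#'   thresholds (money per QALY). Default `c(15000, 20000, 30000)`.
#' @param horizon_mode `"lifetime"` (run to `end_age`) or `"ten_year"`
#'   (truncate at 10 cycles).
#' @param risk_scale `"ten_year"` (annualise the 10-year fracture risk by
#'   constant-hazard compounding) or `"lifetime"` (linearly extrapolate the
#'   10-year risk to the model horizon first, then annualise over the horizon).
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(discount_rate = 0.035, start_age = 40, end_age = 100,
                         cycle_length = 1, cohort_size = 1000,
                         fracture_type = c("MOF", "HF"),
                         thresholds = c(15000, 20000, 30000),
                         horizon_mode = c("lifetime", "ten_year"),
                         risk_scale = c("ten_year", "lifetime")) {
  fracture_type <- match.arg(fracture_type)
  horizon_mode <- match.arg(horizon_mode)
  risk_scale <- match.arg(risk_scale)
  if (!is.numeric(discount_rate) || discount_rate < 0 || discount_rate >= 1)
    stop("'discount_rate' must satisfy 0 <= r < 1", call. = FALSE)
  if (start_age >= end_age) stop("'start_age' must be below 'end_age'", call. = FALSE)
  if (cycle_length != 1) stop("'cycle_length' is fixed at 1 year", call. = FALSE)
  if (cohort_size <= 0) stop("'cohort_size' must be positive", call. = FALSE)
  if (any(thresholds <= 0) || is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be strictly positive and strictly increasing", call. = FALSE)
  structure(list(discount_rate = discount_rate, start_age = start_age,
                 end_age = end_age, cycle_length = cycle_length,
                 cohort_size = cohort_size, fracture_type = fracture_type,
                 thresholds = thresholds, horizon_mode = horizon_mode,
                 risk_scale = risk_scale),
            class = "model_config")
}

#' Screening-test profile for one assessment strategy
#'
#' @param screened_fraction Proportion of the cohort that receives the risk
#'   score (1.0 for universal strategies; the current-practice strategy reaches
#'   about 3% of 40-49 year olds).
#' @param sensitivity,specificity Test accuracy against the true low-BMD
#'   (osteoporosis or osteopenia) status, both in `[0, 1]`.
#' @param tool One of `"QFracture"`, `"IDFracture"`, `"DXA_direct"`. With
#'   `"DXA_direct"` the risk-score stage is skipped and every screened person
#'   goes straight to a (perfectly accurate) DXA scan.
#'
#' @return An object of class `screening_profile`.
#' @export
screening_profile <- function(screened_fraction, sensitivity, specificity,
                              tool = c("QFracture", "IDFracture", "DXA_direct")) {
  tool <- match.arg(tool)
  check_prob(screened_fraction, "screened_fraction")
  check_prob(sensitivity, "sensitivity")
  check_prob(specificity, "specificity")
  structure(list(screened_fraction = screened_fraction, sensitivity = sensitivity,
                 specificity = specificity, tool = tool),
            class = "screening_profile")
}

#' Epidemiological parameters
#'
#' Baseline BMD-category prevalences, the fraction of never-fracturing persons,
#' 10-year fracture risks by BMD category, treatment effects, adherence, and
#' the age-indexed background mortality table with fracture-related
#' multipliers.
#'
#' @param prev_osteoporosis,prev_osteopenia,prev_normal Baseline prevalences of
#'   the three BMD categories; must sum to 1.
#' @param frac_no_fracture Proportion of untreated and normal-BMD persons
#'   allocated to the lifetime 'no fracture' state at baseline.
#' @param p10_fracture_by_state Named numeric vector with elements
#'   `osteoporosis`, `osteopenia`, `normal`: 10-year fracture probabilities.
#' @param refracture_annual Annual re-fracture probability from the
#'   post-fracture state.
#' @param rr_bisphosphonate Relative risk of fracture on bisphosphonate (plus
#'   vitamin D/calcium) treatment, in `(0, 1]`.
#' @param rr_vitd_calcium Relative risk of fracture on vitamin D/calcium alone.
#' @param adherence_annual Probability of remaining on treatment each cycle.
#' @param background_mortality Data frame with columns `age` (integer years)
#'   and `prob` (annual death probability).
#' @param fracture_mortality_multiplier Multiplier on background mortality
#'   during the fracture-year state (>= 1 typically).
#' @param postfracture_mortality_multiplier Multiplier thereafter.
#' @param sex_fracture_multiplier,sex_mortality_multiplier Named vectors
#'   (`men`, `women`, `all`) of scalar multipliers used by subgroup analyses.
#'
#' @return An object of class `epidemiology_params`.
#' @export
epidemiology_params <- function(prev_osteoporosis, prev_osteopenia, prev_normal,
                                frac_no_fracture, p10_fracture_by_state,
                                refracture_annual, rr_bisphosphonate,
                                rr_vitd_calcium, adherence_annual,
                                background_mortality,
                                fracture_mortality_multiplier,
                                postfracture_mortality_multiplier,
                                sex_fracture_multiplier = c(men = 1, women = 1, all = 1),
                                sex_mortality_multiplier = c(men = 1, women = 1, all = 1)) {
  check_prob(prev_osteoporosis, "prev_osteoporosis")
  check_prob(prev_osteopenia, "prev_osteopenia")
  check_prob(prev_normal, "prev_normal")
  if (abs(prev_osteoporosis + prev_osteopenia + prev_normal - 1) > 1e-9)
    stop("BMD prevalences must sum to 1 (got ",
         signif(prev_osteoporosis + prev_osteopenia + prev_normal, 12), ")",
         call. = FALSE)
  check_prob(frac_no_fracture, "frac_no_fracture")
  need <- c("osteoporosis", "osteopenia", "normal")
  if (!all(need %in% names(p10_fracture_by_state)))
    stop("'p10_fracture_by_state' needs elements: ", paste(need, collapse = ", "),
         call. = FALSE)
  p10_fracture_by_state <- p10_fracture_by_state[need]
  check_prob(p10_fracture_by_state, "p10_fracture_by_state")
  check_prob(refracture_annual, "refracture_annual")
  check_prob(rr_bisphosphonate, "rr_bisphosphonate", allow_zero = FALSE)
  check_prob(rr_vitd_calcium, "rr_vitd_calcium", allow_zero = FALSE)
  check_prob(adherence_annual, "adherence_annual")
  if (!is.data.frame(background_mortality) ||
      !all(c("age", "prob") %in% names(background_mortality)))
    stop("'background_mortality' must be a data frame with columns age, prob",
         call. = FALSE)
  check_prob(background_mortality$prob, "background_mortality$prob")
  check_nonneg(fracture_mortality_multiplier, "fracture_mortality_multiplier")
  check_nonneg(postfracture_mortality_multiplier, "postfracture_mortality_multiplier")
  for (nm in c("men", "women", "all")) {
    if (!nm %in% names(sex_fracture_multiplier) ||
        !nm %in% names(sex_mortality_multiplier))
      stop("sex multipliers need elements men, women, all", call. = FALSE)
  }
  structure(list(prev_osteoporosis = prev_osteoporosis,
                 prev_osteopenia = prev_osteopenia,
                 prev_normal = prev_normal,
                 frac_no_fracture = frac_no_fracture,
                 p10_fracture_by_state = p10_fracture_by_state,
                 refracture_annual = refracture_annual,
                 rr_bisphosphonate = rr_bisphosphonate,
                 rr_vitd_calcium = rr_vitd_calcium,
                 adherence_annual = adherence_annual,
                 background_mortality = {
                   bm <- background_mortality[order(background_mortality$age),
                                              c("age", "prob")]
                   rownames(bm) <- NULL
                   bm
                 },
                 fracture_mortality_multiplier = fracture_mortality_multiplier,
                 postfracture_mortality_multiplier = postfracture_mortality_multiplier,
                 sex_fracture_multiplier = sex_fracture_multiplier,
                 sex_mortality_multiplier = sex_mortality_multiplier),
            class = "epidemiology_params")
}

#' Unit costs (GBP, 2021/22 prices)
#'
#' @param cost_risk_score Cost per risk-score assessment.
#' @param cost_dxa Cost per DXA scan.
#' @param cost_treat_osteoporosis_annual Annual cost of bisphosphonate plus
#'   vitamin D and calcium.
#' @param cost_treat_osteopenia_annual Annual cost of vitamin D and calcium.
#' @param cost_fracture_year1 Healthcare cost in the year the fracture occurs.
#' @param cost_postfracture_annual Annual cost in every post-fracture year
#'   (held constant over time, equal to the year-2 cost).
#'
#' @return An object of class `cost_params`.
#' @export
cost_params <- function(cost_risk_score, cost_dxa,
                        cost_treat_osteoporosis_annual,
                        cost_treat_osteopenia_annual,
                        cost_fracture_year1, cost_postfracture_annual) {
  vals <- list(cost_risk_score = cost_risk_score, cost_dxa = cost_dxa,
               cost_treat_osteoporosis_annual = cost_treat_osteoporosis_annual,
               cost_treat_osteopenia_annual = cost_treat_osteopenia_annual,
               cost_fracture_year1 = cost_fracture_year1,
               cost_postfracture_annual = cost_postfracture_annual)
  for (nm in names(vals)) check_nonneg(vals[[nm]], nm)
  structure(vals, class = "cost_params")
}

#' Utility parameters
#'
#' Age-specific baseline utilities (EQ-5D-like, 0 = death, 1 = full health)
#' with proportional multipliers for the fracture year and for subsequent
#' post-fracture years. Treated and untreated non-fractured states share the
#' fracture-free baseline utility; the dead state has utility 0.
#'
#' @param baseline_utility_by_age Data frame with columns `age`, `utility`.
#' @param fracture_year_multiplier Proportion of baseline utility retained in
#'   the fracture-year state.
#' @param postfracture_multiplier Proportion retained in the post-fracture
#'   state.
#'
#' @return An object of class `utility_params`.
#' @export
utility_params <- function(baseline_utility_by_age, fracture_year_multiplier,
                           postfracture_multiplier) {
  if (!is.data.frame(baseline_utility_by_age) ||
      !all(c("age", "utility") %in% names(baseline_utility_by_age)))
    stop("'baseline_utility_by_age' must be a data frame with columns age, utility",
         call. = FALSE)
  check_prob(baseline_utility_by_age$utility, "baseline_utility_by_age$utility")
  check_prob(fracture_year_multiplier, "fracture_year_multiplier")
  check_prob(postfracture_multiplier, "postfracture_multiplier")
  structure(list(baseline_utility_by_age = {
                   ut <- baseline_utility_by_age[order(baseline_utility_by_age$age),
                                                 c("age", "utility")]
                   rownames(ut) <- NULL
                   ut
                 },
                 fracture_year_multiplier = fracture_year_multiplier,
                 postfracture_multiplier = postfracture_multiplier),
            class = "utility_params")
}

#' Assemble a parameter bundle
#'
#' The bundle aggregates every model input: configuration, per-strategy
#' screening profiles (`S1` current practice QFracture, `S2` universal
#' IDFracture, `S3` universal DXA), epidemiology, costs, utilities and the
#' per-group coefficients of variation used by the probabilistic sensitivity
#' analysis. Validated on construction.
#'
#' @param config A [model_config()].
#' @param screening Named list with exactly the elements `S1`, `S2`, `S3`,
#'   each a [screening_profile()].
#' @param epidemiology An [epidemiology_params()].
#' @param costs A [cost_params()].
#' @param utilities A [utility_params()].
#' @param uncertainty Named numeric vector of coefficients of variation per
#'   parameter group (`screening`, `prevalence`, `fracture_risk`,
#'   `treatment_effect`, `adherence`, `mortality`, `utilities`, `costs`).
#'   Missing groups default to 0.2.
#'
#' @return An object of class `parameter_bundle`.
#' @export
parameter_bundle <- function(config, screening, epidemiology, costs, utilities,
                             uncertainty = default_uncertainty()) {
  unc <- default_uncertainty()
  unc[names(uncertainty)] <- uncertainty
  b <- structure(list(config = config, screening = screening,
                      epidemiology = epidemiology, costs = costs,
                      utilities = utilities, uncertainty = unc),
                 class = "parameter_bundle")
  validate_bundle(b)
  b
}

#' @rdname parameter_bundle
#' @export
default_uncertainty <- function() {
  c(screening = 0.2, prevalence = 0.2, fracture_risk = 0.2,
    treatment_effect = 0.2, adherence = 0.2, mortality = 0.2,
    utilities = 0.2, costs = 0.2)
}

#' Validate a parameter bundle
#'
#' Checks every component invariant: component classes, the exact strategy-id
#' set, prevalence closure, probability ranges, and that the mortality and
#' utility tables cover every integer age between `start_age` and `end_age`.
#'
#' @param bundle A [parameter_bundle()].
#' @return `TRUE` invisibly; errors name the offending field.
#' @export
validate_bundle <- function(bundle) {
  if (!inherits(bundle, "parameter_bundle"))
    stop("not a parameter_bundle", call. = FALSE)
  if (!inherits(bundle$config, "model_config"))
    stop("'config' is not a model_config", call. = FALSE)
  if (!setequal(names(bundle$screening), c("S1", "S2", "S3")) ||
      length(bundle$screening) != 3)
    stop("'screening' must contain exactly the strategies S1, S2, S3", call. = FALSE)
  for (id in c("S1", "S2", "S3"))
    if (!inherits(bundle$screening[[id]], "screening_profile"))
      stop(sprintf("screening$%s is not a screening_profile", id), call. = FALSE)
  if (!inherits(bundle$epidemiology, "epidemiology_params"))
    stop("'epidemiology' is not epidemiology_params", call. = FALSE)
  if (!inherits(bundle$costs, "cost_params"))
    stop("'costs' is not cost_params", call. = FALSE)
  if (!inherits(bundle$utilities, "utility_params"))
    stop("'utilities' is not utility_params", call. = FALSE)
  ages <- seq(bundle$config$start_age, bundle$config$end_age)
  miss <- setdiff(ages, bundle$epidemiology$background_mortality$age)
  if (length(miss))
    stop("background_mortality table is missing age ", miss[1], call. = FALSE)
  miss_u <- setdiff(ages, bundle$utilities$baseline_utility_by_age$age)
  if (length(miss_u))
    stop("baseline_utility_by_age table is missing age ", miss_u[1], call. = FALSE)
  prev <- bundle$epidemiology$prev_osteoporosis +
    bundle$epidemiology$prev_osteopenia + bundle$epidemiology$prev_normal
  if (abs(prev - 1) > 1e-9)
    stop("BMD prevalences must sum to 1", call. = FALSE)
  if (anyNA(bundle$uncertainty) || any(bundle$uncertainty < 0))
    stop("'uncertainty' CVs must be non-negative", call. = FALSE)
  if (!bundle$config$horizon_mode %in% c("lifetime", "ten_year"))
    stop("config$horizon_mode must be 'lifetime' or 'ten_year'", call. = FALSE)
  if (!bundle$config$risk_scale %in% c("ten_year", "lifetime"))
    stop("config$risk_scale must be 'ten_year' or 'lifetime'", call. = FALSE)
  if (!bundle$config$fracture_type %in% c("MOF", "HF"))
    stop("config$fracture_type must be 'MOF' or 'HF'", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.parameter_bundle <- function(x, ...) {
  cfg <- x$config
  cat("<parameter_bundle>\n")
  cat(sprintf("  cohort: %g persons entering at age %g, followed to %g (%s horizon)\n",
              cfg$cohort_size, cfg$start_age, cfg$end_age, cfg$horizon_mode))
  cat(sprintf("  endpoint: %s | discount %.1f%% | thresholds: %s GBP/QALY\n",
              cfg$fracture_type, 100 * cfg$discount_rate,
              paste(format(cfg$thresholds, big.mark = ","), collapse = ", ")))
  for (id in c("S1", "S2", "S3")) {
    s <- x$screening[[id]]
    cat(sprintf("  %s: %s, screened %.0f%%, sens %.2f, spec %.2f\n", id, s$tool,
                100 * s$screened_fraction, s$sensitivity, s$specificity))
  }
  invisible(x)
}

# ---- risk-scale conversions -------------------------------------------------

#' Convert a 10-year probability to an annual probability
#'
#' Constant-hazard compounding: the annual probability `p1` satisfies
#' `(1 - p1)^10 = 1 - p10`, i.e. `p1 = 1 - (1 - p10)^(1/10)`.
#'
#' @param p10 10-year event probability, in `[0, 1]`.
#' @return Annual probability in `[0, 1]`, monotone in `p10`.
#' @examples
#' annualize_risk(0.10)  # 0.010481
#' @export
annualize_risk <- function(p10) {
  check_prob(p10, "p10")
  1 - (1 - p10)^(1 / 10)
}

#' Linearly extrapolate a 10-year risk to a longer horizon
#'
#' `min(1, p10 * horizon_years / 10)` — the linear lifetime-risk scaling used
#' as a sensitivity analysis on the 10-year fracture risk.
#'
#' @param p10 10-year event probability in `[0, 1]`.
#' @param horizon_years Positive horizon length in years.
#' @return Horizon probability, capped at 1.
#' @export
extrapolate_lifetime_risk <- function(p10, horizon_years) {
  check_prob(p10, "p10")
  if (any(horizon_years <= 0)) stop("'horizon_years' must be positive", call. = FALSE)
  pmin(p10 * horizon_years / 10, 1)
}

#' Moment-matched beta parameters
#'
#' Given a mean and coefficient of variation, returns the `(shape1, shape2)`
#' pair of the beta distribution with that mean and variance
#' `(cv * mean)^2`: `shape1 = mean * k`, `shape2 = (1 - mean) * k` with
#' `k = mean (1 - mean) / var - 1`.
#'
#' @param mean Target mean, strictly inside `(0, 1)`.
#' @param cv Coefficient of variation (> 0); the implied variance must be
#'   below `mean * (1 - mean)`.
#' @return Named numeric vector `c(shape1, shape2)`, both positive.
#' @examples
#' beta_from_mean_cv(0.5, 0.2)  # shape1 = shape2 = 12
#' @export
beta_from_mean_cv <- function(mean, cv) {
  if (mean <= 0 || mean >= 1)
    stop("beta moment matching needs 0 < mean < 1 (got ", mean, ")", call. = FALSE)
  if (cv <= 0) stop("'cv' must be positive", call. = FALSE)
  v <- (cv * mean)^2
  k <- mean * (1 - mean) / v - 1
  if (k <= 0)
    stop("variance ", signif(v, 6), " too large for a beta with mean ", mean,
         call. = FALSE)
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

#' Moment-matched gamma parameters
#'
#' Returns `(shape, scale) = (1/cv^2, mean * cv^2)`, the gamma distribution
#' with the requested mean and standard deviation `cv * mean`.
#'
#' @param mean Target mean (> 0).
#' @param cv Coefficient of variation (> 0).
#' @return Named numeric vector `c(shape, scale)` with `shape * scale == mean`.
#' @examples
#' gamma_from_mean_cv(100, 0.2)  # shape 25, scale 4
#' @export
gamma_from_mean_cv <- function(mean, cv) {
  if (mean <= 0) stop("'mean' must be positive", call. = FALSE)
  if (cv <= 0) stop("'cv' must be positive", call. = FALSE)
  c(shape = 1 / cv^2, scale = mean * cv^2)
}

# ---- synthetic generator ----------------------------------------------------

#' Generate a synthetic parameter bundle
#'
#' Stands in for the study's (non-public) supplementary parameter tables.
#' Structural settings follow the published design: cohort of 1000 entering at
#' age 40, followed to age 100, annual cycles, 3.5% discounting, thresholds of
#' 15/20/30 thousand GBP per QALY, S1 screened fraction 3%, S2 and S3
#' universal. Epidemiological, cost and utility values are field-realistic
#' synthetic defaults (see the package vignette); the seed applies small
#' multiplicative jitter so different seeds give different, equally valid
#' bundles while every invariant (prevalence closure, fracture-risk ordering
#' osteoporosis > osteopenia > normal, strictly increasing mortality) holds.
#'
#' @param seed Integer seed; the same seed always returns an identical bundle.
#' @param scenario `"mof"` (major osteoporotic fracture, default) or `"hf"`
#'   (hip fracture). Unknown labels are rejected.
#' @return A validated [parameter_bundle()].
#' @export
generate_parameter_set <- function(seed = 1L, scenario = "mof") {
  if (!is.character(scenario) || length(scenario) != 1 ||
      !tolower(scenario) %in% c("mof", "hf", "base"))
    stop("unknown scenario label: ", paste(scenario, collapse = ", "),
         "; expected 'mof' or 'hf'", call. = FALSE)
  scenario <- if (tolower(scenario) == "hf") "hf" else "mof"
  hf <- scenario == "hf"

  with_seed(seed, {
    jit <- function(n, sd) exp(stats::rnorm(n, 0, sd))

    prev <- c(op = 0.20, pe = 0.40, nm = 0.40) * jit(3, 0.03)
    prev <- prev / sum(prev)

    p10_base <- if (hf) c(osteoporosis = 0.07, osteopenia = 0.03, normal = 0.01)
                else c(osteoporosis = 0.25, osteopenia = 0.15, normal = 0.06)
    p10 <- pmin(0.95, p10_base * jit(3, 0.04))
    p10 <- sort(p10, decreasing = TRUE)             # enforce op > pe > nm
    names(p10) <- c("osteoporosis", "osteopenia", "normal")

    ages <- 40:100
    m40 <- 0.006 * jit(1, 0.03)
    m100 <- 0.40 * jit(1, 0.03)
    # Gompertz-like log-linear hazard through the two anchors
    mort <- exp(log(m40) + (ages - 40) / 60 * (log(m100) - log(m40)))
    mortality <- data.frame(age = ages, prob = pmin(mort, 0.999))

    util <- data.frame(age = ages,
                       utility = pmin(1, (0.85 - 0.0028 * (ages - 40)) * jit(1, 0.01)))

    epi <- epidemiology_params(
      prev_osteoporosis = prev[["op"]], prev_osteopenia = prev[["pe"]],
      prev_normal = prev[["nm"]],
      frac_no_fracture = 0.30,
      p10_fracture_by_state = p10,
      refracture_annual = if (hf) 0.02 else 0.05,
      rr_bisphosphonate = 0.55, rr_vitd_calcium = 0.80,
      adherence_annual = 0.80,
      background_mortality = mortality,
      fracture_mortality_multiplier = if (hf) 2.5 else 1.5,
      postfracture_mortality_multiplier = if (hf) 1.5 else 1.1,
      sex_fracture_multiplier = c(men = 0.90, women = 1.15, all = 1),
      sex_mortality_multiplier = c(men = 1.20, women = 0.90, all = 1))

    # generic alendronate plus vitamin D/calcium at current UK prices;
    # fracture costs reflect the linked primary/secondary-care costing of an
    # ID cohort (year 1 vs constant later years)
    costs <- cost_params(
      cost_risk_score = 10, cost_dxa = 80,
      cost_treat_osteoporosis_annual = 55,
      cost_treat_osteopenia_annual = 40,
      cost_fracture_year1 = if (hf) 14000 else 3800,
      cost_postfracture_annual = if (hf) 2800 else 1200)

    utils_p <- utility_params(
      baseline_utility_by_age = util,
      fracture_year_multiplier = if (hf) 0.60 else 0.77,
      postfracture_multiplier = if (hf) 0.80 else 0.92)

    screening <- list(
      S1 = screening_profile(0.03, 0.60, 0.75, "QFracture"),
      S2 = screening_profile(1.00, 0.72, 0.80, "IDFracture"),
      S3 = screening_profile(1.00, 1.00, 1.00, "DXA_direct"))

    parameter_bundle(
      config = model_config(fracture_type = if (hf) "HF" else "MOF"),
      screening = screening, epidemiology = epi, costs = costs,
      utilities = utils_p)
  })
}

# ---- serialization ----------------------------------------------------------

#' Save a parameter bundle as JSON
#'
#' Full-precision JSON with a fixed key layout; [load_bundle()] restores the
#' bundle bit-for-bit.
#'
#' @param bundle A validated [parameter_bundle()].
#' @param path File path to write.
#' @return `path` invisibly.
#' @export
save_bundle <- function(bundle, path) {
  validate_bundle(bundle)
  strip <- function(v) {
    if (is.data.frame(v)) v
    else if (is.list(v)) lapply(v, strip)
    else v
  }
  x <- strip(unclass(bundle))
  x$config$thresholds <- I(bundle$config$thresholds)
  # named vectors must become JSON objects, not nameless arrays
  x$epidemiology$p10_fracture_by_state <-
    as.list(bundle$epidemiology$p10_fracture_by_state)
  x$epidemiology$sex_fracture_multiplier <-
    as.list(bundle$epidemiology$sex_fracture_multiplier)
  x$epidemiology$sex_mortality_multiplier <-
    as.list(bundle$epidemiology$sex_mortality_multiplier)
  x$uncertainty <- as.list(bundle$uncertainty)
  # digits = I(17): significant digits, enough for exact double round trips
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop("cannot parse bundle file '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  need <- c("config", "screening", "epidemiology", "costs", "utilities", "uncertainty")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("bundle file is missing field '", miss[1], "'", call. = FALSE)
  cfg <- x$config
  config <- model_config(discount_rate = as.numeric(cfg$discount_rate),
                         start_age = as.numeric(cfg$start_age),
                         end_age = as.numeric(cfg$end_age),
                         cycle_length = as.numeric(cfg$cycle_length),
                         cohort_size = as.numeric(cfg$cohort_size),
                         fracture_type = cfg$fracture_type,
                         thresholds = as.numeric(cfg$thresholds),
                         horizon_mode = cfg$horizon_mode, risk_scale = cfg$risk_scale)
  screening <- lapply(x$screening, function(s)
    screening_profile(s$screened_fraction, s$sensitivity, s$specificity, s$tool))
  e <- x$epidemiology
  epi <- epidemiology_params(
    prev_osteoporosis = e$prev_osteoporosis, prev_osteopenia = e$prev_osteopenia,
    prev_normal = e$prev_normal, frac_no_fracture = e$frac_no_fracture,
    p10_fracture_by_state = unlist(e$p10_fracture_by_state),
    refracture_annual = e$refracture_annual,
    rr_bisphosphonate = e$rr_bisphosphonate, rr_vitd_calcium = e$rr_vitd_calcium,
    adherence_annual = e$adherence_annual,
    background_mortality = as.data.frame(e$background_mortality),
    fracture_mortality_multiplier = e$fracture_mortality_multiplier,
    postfracture_mortality_multiplier = e$postfracture_mortality_multiplier,
    sex_fracture_multiplier = unlist(e$sex_fracture_multiplier),
    sex_mortality_multiplier = unlist(e$sex_mortality_multiplier))
  costs <- do.call(cost_params, as.list(x$costs))
  u <- x$utilities
  utilities <- utility_params(as.data.frame(u$baseline_utility_by_age),
                              u$fracture_year_multiplier, u$postfracture_multiplier)
  parameter_bundle(config, screening, epi, costs, utilities,
                   uncertainty = unlist(x$uncertainty))
}

#' Read a two-column age table (CSV)
#'
#' Imports mortality (`age, prob`) or utility (`age, utility`) tables from a
#' plain two-column CSV, for splicing into a bundle.
#'
#' @param path CSV path; first column age, second column value.
#' @param value_name Name for the value column (`"prob"` or `"utility"`).
#' @return Data frame with columns `age` and `value_name`.
#' @export
read_age_table <- function(path, value_name = "prob") {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("age table must have two columns", call. = FALSE)
  out <- data.frame(age = as.numeric(d[[1]]), value = as.numeric(d[[2]]))
  names(out)[2] <- value_name
  out
}
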