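# Hand-authored reference bundle used by the golden tests: flat tables and
# round numbers so expectations can be derived by hand.
reference_bundle <- function(fracture_type = "MOF",
                             frac_no_fracture = 0.3,
                             adherence = 0.8) {
  ages <- 40:100
  parameter_bundle(
    config = model_config(fracture_type = fracture_type),
    screening = list(
      S1 = screening_profile(0.03, 0.60, 0.75, "QFracture"),
      S2 = screening_profile(1.00, 0.80, 0.90, "IDFracture"),
      S3 = screening_profile(1.00, 1.00, 1.00, "DXA_direct")),
    epidemiology = epidemiology_params(
      prev_osteoporosis = 0.2, prev_osteopenia = 0.3, prev_normal = 0.5,
      frac_no_fracture = frac_no_fracture,
      p10_fracture_by_state = c(osteoporosis = 0.20, osteopenia = 0.10,
                                normal = 0.04),
      refracture_annual = 0.05,
      rr_bisphosphonate = 0.5, rr_vitd_calcium = 0.8,
      adherence_annual = adherence,
      background_mortality = data.frame(age = ages,
                                        prob = 0.005 + 0.004 * (ages - 40)),
      fracture_mortality_multiplier = 1.5,
      postfracture_mortality_multiplier = 1.1,
      sex_fracture_multiplier = c(men = 0.9, women = 1.15, all = 1),
      sex_mortality_multiplier = c(men = 1.2, women = 0.9, all = 1)),
    costs = cost_params(10, 80, 55, 40, 3800, 1200),
    utilities = utility_params(
      baseline_utility_by_age = data.frame(age = ages, utility = 0.8),
      fracture_year_multiplier = 0.75,
      postfracture_multiplier = 0.9))
}

# bundle with no fracture risk, no mortality, unit utility: closed-form QALYs
degenerate_bundle <- function(discount_rate = 0.035) {
  ages <- 40:100
  b <- reference_bundle()
  b$config$discount_rate <- discount_rate
  b$epidemiology$p10_fracture_by_state[] <- 0
  b$epidemiology$refracture_annual <- 0
  b$epidemiology$background_mortality$prob[] <- 0
  b$utilities$baseline_utility_by_age$utility[] <- 1
  b$utilities$fracture_year_multiplier <- 1
  b$utilities$postfracture_multiplier <- 1
  validate_bundle(b)
  b
}

# random valid bundle for property tests (all invariants hold by construction)
random_bundle <- function() {
  ages <- 40:100
  prev <- stats::runif(3); prev <- prev / sum(prev)
  p10 <- sort(stats::runif(3, 0.01, 0.6), decreasing = TRUE)
  names(p10) <- c("osteoporosis", "osteopenia", "normal")
  parameter_bundle(
    config = model_config(discount_rate = stats::runif(1, 0, 0.1)),
    screening = list(
      S1 = screening_profile(stats::runif(1), stats::runif(1), stats::runif(1),
                             "QFracture"),
      S2 = screening_profile(1, stats::runif(1), stats::runif(1), "IDFracture"),
      S3 = screening_profile(1, 1, 1, "DXA_direct")),
    epidemiology = epidemiology_params(
      prev_osteoporosis = prev[1], prev_osteopenia = prev[2], prev_normal = prev[3],
      frac_no_fracture = stats::runif(1, 0, 0.6),
      p10_fracture_by_state = p10,
      refracture_annual = stats::runif(1, 0, 0.2),
      rr_bisphosphonate = stats::runif(1, 0.3, 1),
      rr_vitd_calcium = stats::runif(1, 0.5, 1),
      adherence_annual = stats::runif(1, 0.5, 1),
      background_mortality = data.frame(
        age = ages, prob = seq(stats::runif(1, 0.001, 0.01),
                               stats::runif(1, 0.2, 0.5), length.out = 61)),
      fracture_mortality_multiplier = stats::runif(1, 1, 2),
      postfracture_mortality_multiplier = stats::runif(1, 1, 1.5)),
    costs = cost_params(stats::runif(1, 0, 20), stats::runif(1, 20, 150),
                        stats::runif(1, 10, 200), stats::runif(1, 10, 100),
                        stats::runif(1, 1000, 20000), stats::runif(1, 100, 4000)),
    utilities = utility_params(
      baseline_utility_by_age = data.frame(
        age = ages, utility = stats::runif(1, 0.5, 0.95) - 0.001 * (ages - 40)),
      fracture_year_multiplier = stats::runif(1, 0.4, 1),
      postfracture_multiplier = stats::runif(1, 0.6, 1)))
}

reference_increments <- function() {
  utils::read.csv(system.file("extdata", "reference_base_case_increments.csv",
                              package = "osteocea"))
}
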