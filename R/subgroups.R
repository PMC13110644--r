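#' NICE-derived screened fraction for an age/sex band
#'
#' Maps the recognised age bands onto the screened-fraction ranges used for
#' the current-practice strategy: ages 40-49 (either sex) 1%-5% with base 3%;
#' women 50-64 and men 50-74, 35%-50% with the midpoint 42.5% as base; all
#' women from 65 and all men from 75 (i.e. 100%). Bands outside 40-79, or not
#' matching a recognised band for the given sex, are rejected.
#'
#' @param sex `"men"`, `"women"` or `"all"` (`"all"` recognised for the
#'   40-49 band only, where the mapping is sex-independent).
#' @param age_low,age_high Band limits in years, `age_low < age_high`.
#' @return Object of class `subgroup_spec`: list with `sex`, `age_low`,
#'   `age_high`, `screened_fraction_low`, `screened_fraction_base`,
#'   `screened_fraction_high`.
#' @export
subgroup_screen_fraction <- function(sex = c("men", "women", "all"),
                                     age_low, age_high) {
  sex <- match.arg(sex)
  if (age_low >= age_high) stop("'age_low' must be below 'age_high'", call. = FALSE)
  if (age_low < 40 || age_high > 79)
    stop("age band ", age_low, "-", age_high, " outside the supported 40-79 range",
         call. = FALSE)
  band_is <- function(lo, hi) age_low == lo && age_high == hi
  frac <-
    if (band_is(40, 49)) c(0.01, 0.03, 0.05)
    else if (sex == "women" && band_is(50, 64)) c(0.35, 0.425, 0.50)
    else if (sex == "men" && band_is(50, 74)) c(0.35, 0.425, 0.50)
    else if (sex == "women" && band_is(65, 79)) c(1, 1, 1)
    else if (sex == "men" && band_is(75, 79)) c(1, 1, 1)
    else stop("unrecognised band ", age_low, "-", age_high, " for ", sex,
              call. = FALSE)
  structure(list(sex = sex, age_low = age_low, age_high = age_high,
                 screened_fraction_low = frac[1],
                 screened_fraction_base = frac[2],
                 screened_fraction_high = frac[3]),
            class = "subgroup_spec")
}

#' Default subgroup grid
#'
#' The five recognised age/sex bands: 40-49 (both sexes pooled), women 50-64,
#' men 50-74, women 65-79, men 75-79.
#'
#' @return List of [subgroup_screen_fraction()] specs.
#' @export
default_subgroup_specs <- function() {
  list(subgroup_screen_fraction("all", 40, 49),
       subgroup_screen_fraction("women", 50, 64),
       subgroup_screen_fraction("men", 50, 74),
       subgroup_screen_fraction("women", 65, 79),
       subgroup_screen_fraction("men", 75, 79))
}

# bundle adjusted to a subgroup: entry age, S1 screened fraction, sex scaling
subgroup_bundle <- function(bundle, spec,
                            screened_fraction = spec$screened_fraction_base) {
  b <- bundle
  b$config$start_age <- spec$age_low
  b$screening$S1$screened_fraction <- screened_fraction
  fx <- b$epidemiology$sex_fracture_multiplier[[spec$sex]]
  mt <- b$epidemiology$sex_mortality_multiplier[[spec$sex]]
  b$epidemiology$p10_fracture_by_state[] <-
    pmin(b$epidemiology$p10_fracture_by_state * fx, 1)
  b$epidemiology$background_mortality$prob <-
    pmin(b$epidemiology$background_mortality$prob * mt, 1)
  validate_bundle(b)
  b
}

#' Age/sex subgroup analyses
#'
#' Re-runs the full pipeline per subgroup: the cohort enters at the band's
#' lower age (still followed to `end_age`), the current-practice screened
#' fraction is taken from the band's NICE-derived base value, and the
#' fracture risks and background mortality are scaled by the bundle's
#' sex-specific multipliers.
#'
#' @param bundle A validated [parameter_bundle()].
#' @param specs List of [subgroup_screen_fraction()] specs; defaults to
#'   [default_subgroup_specs()].
#' @param comparator Comparator strategy id.
#' @return Data frame: sex, age band and S1 screened fraction columns followed
#'   by the [compare_strategies()] columns.
#' @export
run_subgroups <- function(bundle, specs = default_subgroup_specs(),
                          comparator = "S1") {
  validate_bundle(bundle)
  do.call(rbind, lapply(specs, function(sp) {
    res <- run_cea(subgroup_bundle(bundle, sp), comparator)
    cbind(sex = sp$sex, age_low = sp$age_low, age_high = sp$age_high,
          s1_screened_fraction = sp$screened_fraction_base,
          as.data.frame(res$comparisons))
  }))
}
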