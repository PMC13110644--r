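#' Health-state labels of the Markov model
#'
#' The nine states, in model order: untreated osteoporosis, treated
#' osteoporosis, untreated osteopenia, treated osteopenia, normal BMD,
#' no fracture, fracture (one-year tunnel), post fracture, dead.
#'
#' @return Character vector of length 9.
#' @export
health_states <- function() {
  c("untreated_osteoporosis", "treated_osteoporosis",
    "untreated_osteopenia", "treated_osteopenia",
    "normal_bmd", "no_fracture", "fracture", "post_fracture", "dead")
}

#' State-occupancy vector
#'
#' @param occupancy Numeric vector of persons per state; either length 9 in
#'   [health_states()] order or named by state.
#' @param cohort_size Expected total (checked to 1e-9 relative).
#' @return Named numeric vector of class `state_distribution`.
#' @export
state_distribution <- function(occupancy, cohort_size = sum(occupancy)) {
  st <- health_states()
  if (!is.null(names(occupancy))) {
    miss <- setdiff(st, names(occupancy))
    if (length(miss)) stop("occupancy is missing state '", miss[1], "'", call. = FALSE)
    occupancy <- occupancy[st]
  } else if (length(occupancy) == length(st)) {
    names(occupancy) <- st
  } else {
    stop("occupancy must have ", length(st), " elements", call. = FALSE)
  }
  if (any(occupancy < -1e-12)) stop("occupancy must be non-negative", call. = FALSE)
  occupancy <- pmax(occupancy, 0)
  if (abs(sum(occupancy) - cohort_size) > 1e-9 * max(1, cohort_size))
    stop("occupancy sums to ", sum(occupancy), ", expected ", cohort_size,
         call. = FALSE)
  structure(occupancy, class = "state_distribution")
}

#' Probability of a positive risk score
#'
#' Marginal positivity of a binary test with the given sensitivity and
#' specificity against a condition (low BMD) of the given prevalence:
#' `prev * sens + (1 - prev) * (1 - spec)`.
#'
#' @param prev_low_bmd Prevalence of low BMD (osteoporosis or osteopenia).
#' @param sens,spec Test sensitivity and specificity.
#' @return Proportion testing positive, in `[0, 1]`.
#' @export
screen_positive_rate <- function(prev_low_bmd, sens, spec) {
  check_prob(prev_low_bmd, "prev_low_bmd")
  check_prob(sens, "sens")
  check_prob(spec, "spec")
  prev_low_bmd * sens + (1 - prev_low_bmd) * (1 - spec)
}

#' Upfront assessment cost of the screening cascade
#'
#' `n_risk_scored * cost_risk_score + n_dxa * cost_dxa`. The direct-DXA
#' strategy carries no risk-score term (`n_risk_scored` is 0 there).
#'
#' @param n_risk_scored Persons receiving the risk score.
#' @param n_dxa Persons receiving a DXA scan.
#' @param costs A [cost_params()].
#' @param strategy_id Strategy label, for error messages.
#' @return Total upfront money (>= 0).
#' @export
upfront_assessment_cost <- function(n_risk_scored, n_dxa, costs,
                                    strategy_id = NULL) {
  if (n_risk_scored < 0 || n_dxa < 0)
    stop("screening counts must be non-negative",
         if (!is.null(strategy_id)) paste0(" (", strategy_id, ")"), call. = FALSE)
  n_risk_scored * costs$cost_risk_score + n_dxa * costs$cost_dxa
}

#' Run the screening cascade for one strategy
#'
#' Converts a strategy's screening profile plus the cohort's baseline BMD
#' prevalences into the Markov model's initial state distribution, DXA count
#' and upfront assessment cost. The cascade:
#'
#' 1. a fraction `screened_fraction` of the cohort receives the risk score
#'    (for the direct-DXA tool the score stage is skipped and screened persons
#'    go straight to DXA);
#' 2. scored persons test positive with probability `sensitivity` if their
#'    true BMD category is osteoporosis or osteopenia, and `1 - specificity`
#'    if it is normal;
#' 3. positives receive a DXA (assumed perfectly accurate) and are allocated:
#'    osteoporosis to treated osteoporosis, osteopenia to treated osteopenia,
#'    normal BMD back to the normal state untreated;
#' 4. negatives and the unscreened remain untreated in their true category;
#' 5. a fraction `frac_no_fracture` of the at-risk population — treated and
#'    untreated osteoporosis/osteopenia and normal BMD alike — is moved to
#'    the lifetime 'no fracture' state. Persons in that state accrue no
#'    treatment cost, a simplification that slightly understates treatment
#'    spending in the universal strategies (see the package vignette).
#'
#' @param strategy_id One of `"S1"`, `"S2"`, `"S3"`.
#' @param bundle A validated [parameter_bundle()].
#' @return An object of class `screening_outcome`: list with elements
#'   `distribution` ([state_distribution()]), `n_risk_scored`, `n_dxa`,
#'   `upfront_cost`.
#' @export
initial_state_distribution <- function(strategy_id, bundle) {
  if (!strategy_id %in% c("S1", "S2", "S3"))
    stop("unknown strategy id '", strategy_id, "'", call. = FALSE)
  validate_bundle(bundle)
  prof <- bundle$screening[[strategy_id]]
  epi <- bundle$epidemiology
  N <- bundle$config$cohort_size
  s <- prof$screened_fraction

  n_cat <- N * c(op = epi$prev_osteoporosis, pe = epi$prev_osteopenia,
                 nm = epi$prev_normal)
  scored <- s * n_cat

  if (prof$tool == "DXA_direct") {
    n_risk_scored <- 0
    dxa <- scored                       # everyone screened goes straight to DXA
  } else {
    n_risk_scored <- sum(scored)
    dxa <- c(op = scored[["op"]] * prof$sensitivity,
             pe = scored[["pe"]] * prof$sensitivity,
             nm = scored[["nm"]] * (1 - prof$specificity))
  }
  n_dxa <- sum(dxa)

  treated_op <- dxa[["op"]]
  treated_pe <- dxa[["pe"]]
  untreated_op <- n_cat[["op"]] - treated_op
  untreated_pe <- n_cat[["pe"]] - treated_pe
  normal <- n_cat[["nm"]]              # normal-BMD positives return untreated

  f <- epi$frac_no_fracture
  at_risk <- untreated_op + treated_op + untreated_pe + treated_pe + normal
  occ <- c(untreated_osteoporosis = untreated_op,
           treated_osteoporosis = treated_op,
           untreated_osteopenia = untreated_pe,
           treated_osteopenia = treated_pe,
           normal_bmd = normal,
           no_fracture = f * at_risk,
           fracture = 0, post_fracture = 0, dead = 0) * c(rep(1 - f, 5), 1, 1, 1, 1)

  structure(list(distribution = state_distribution(occ, N),
                 n_risk_scored = n_risk_scored,
                 n_dxa = n_dxa,
                 upfront_cost = upfront_assessment_cost(n_risk_scored, n_dxa,
                                                        bundle$costs, strategy_id),
                 strategy_id = strategy_id),
            class = "screening_outcome")
}

#' @export
print.screening_outcome <- function(x, ...) {
  cat(sprintf("<screening_outcome %s> risk-scored %.1f, DXA %.1f, upfront cost %.2f\n",
              x$strategy_id, x$n_risk_scored, x$n_dxa, x$upfront_cost))
  print(round(unclass(x$distribution), 2))
  invisible(x)
}
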