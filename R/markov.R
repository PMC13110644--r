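# state indices (see health_states()): 1 op_untx, 2 op_tx, 3 pe_untx, 4 pe_tx,
# 5 normal, 6 no_fx, 7 fracture, 8 post_fx, 9 dead

#' Discount factor for an annual cycle
#'
#' `(1 + rate)^(-cycle_index)`; cycle 0 is undiscounted (no half-cycle
#' correction is applied anywhere in the model).
#'
#' @param rate Annual discount rate (>= 0).
#' @param cycle_index Integer cycle index (>= 0); vectorised.
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(rate, cycle_index) {
  if (any(rate < 0)) stop("'rate' must be non-negative", call. = FALSE)
  if (any(cycle_index < 0)) stop("'cycle_index' must be non-negative", call. = FALSE)
  (1 + rate)^(-cycle_index)
}

# annual fracture probability per BMD state, honouring the risk-scale switch
annual_fracture_probs <- function(bundle) {
  p10 <- bundle$epidemiology$p10_fracture_by_state
  if (bundle$config$risk_scale == "lifetime") {
    H <- bundle$config$end_age - bundle$config$start_age
    pH <- extrapolate_lifetime_risk(p10, H)
    1 - (1 - pH)^(1 / H)
  } else {
    annualize_risk(p10)
  }
}

mortality_at_age <- function(bundle, age) {
  bm <- bundle$epidemiology$background_mortality
  i <- match(age, bm$age)
  if (anyNA(i)) stop("no background mortality for age ", age[is.na(i)][1],
                     call. = FALSE)
  bm$prob[i]
}

utility_at_age <- function(bundle, age) {
  ut <- bundle$utilities$baseline_utility_by_age
  i <- match(age, ut$age)
  if (anyNA(i)) stop("no baseline utility for age ", age[is.na(i)][1],
                     call. = FALSE)
  ut$utility[i]
}

#' One-cycle transition matrix at a given age
#'
#' Builds the 9x9 row-stochastic matrix for one annual cycle. Competing risks
#' are resolved death-first: background mortality `m(age)` applies to every
#' alive state, and fracture applies to survivors, so an untreated row is
#' `dead = m`, `fracture = (1 - m) p_fx`, `stay = (1 - m)(1 - p_fx)`.
#' Treated rows multiply the fracture probability by the arm's relative risk
#' and route a `(1 - adherence)` share of non-fracturing survivors to the
#' matching untreated state (permanent discontinuation). The 'no fracture'
#' state faces mortality only. The fracture state is a one-cycle tunnel
#' (death at `m * fracture_mortality_multiplier`, remainder to post fracture);
#' the post-fracture state re-fractures with the annual re-fracture
#' probability and dies at `m * postfracture_mortality_multiplier`. Dead is
#' absorbing. Products exceeding 1 are capped with a warning.
#'
#' @param age Integer age within `[start_age, end_age]`.
#' @param bundle A validated [parameter_bundle()].
#' @return 9x9 matrix with dimnames [health_states()], rows summing to 1.
#' @export
build_transition_matrix <- function(age, bundle) {
  if (age < bundle$config$start_age || age > bundle$config$end_age)
    stop("age ", age, " outside the model range", call. = FALSE)
  epi <- bundle$epidemiology
  st <- health_states()
  m <- mortality_at_age(bundle, age)
  p <- annual_fracture_probs(bundle)
  a <- epi$adherence_annual

  cap <- function(x, what) {
    if (x > 1) {
      warning(what, " probability ", signif(x, 4), " capped at 1 (age ", age, ")",
              call. = FALSE)
      1
    } else x
  }

  P <- matrix(0, 9, 9, dimnames = list(st, st))
  bmd_row <- function(p_fx) {
    fx <- (1 - m) * p_fx
    c(stay = 1 - m - fx, fracture = fx, dead = m)
  }
  # untreated rows
  r <- bmd_row(p[["osteoporosis"]]); P[1, c(1, 7, 9)] <- r
  r <- bmd_row(p[["osteopenia"]]);   P[3, c(3, 7, 9)] <- r
  r <- bmd_row(p[["normal"]]);       P[5, c(5, 7, 9)] <- r
  # treated rows: RR on fracture, non-adherent survivors drop to untreated
  treated_row <- function(p_fx, rr) {
    fx <- (1 - m) * cap(rr * p_fx, "treated fracture")
    rest <- 1 - m - fx
    c(stay = rest * a, drop = rest * (1 - a), fracture = fx, dead = m)
  }
  r <- treated_row(p[["osteoporosis"]], epi$rr_bisphosphonate)
  P[2, c(2, 1, 7, 9)] <- r
  r <- treated_row(p[["osteopenia"]], epi$rr_vitd_calcium)
  P[4, c(4, 3, 7, 9)] <- r
  # no fracture: mortality only
  P[6, 6] <- 1 - m; P[6, 9] <- m
  # fracture tunnel
  mf <- cap(m * epi$fracture_mortality_multiplier, "fracture-year death")
  P[7, 8] <- 1 - mf; P[7, 9] <- mf
  # post fracture
  mp <- cap(m * epi$postfracture_mortality_multiplier, "post-fracture death")
  refx <- (1 - mp) * epi$refracture_annual
  P[8, 7] <- refx; P[8, 8] <- 1 - mp - refx; P[8, 9] <- mp
  # dead absorbing
  P[9, 9] <- 1
  P
}

# per-state cost and utility accrual vectors at a given age
state_cost_vector <- function(bundle) {
  cst <- bundle$costs
  c(0, cst$cost_treat_osteoporosis_annual,
    0, cst$cost_treat_osteopenia_annual,
    0, 0, cst$cost_fracture_year1, cst$cost_postfracture_annual, 0)
}

state_utility_vector <- function(bundle, age) {
  u <- utility_at_age(bundle, age)
  ut <- bundle$utilities
  c(u, u, u, u, u, u, u * ut$fracture_year_multiplier,
    u * ut$postfracture_multiplier, 0)
}

n_model_cycles <- function(bundle) {
  if (bundle$config$horizon_mode == "ten_year") 10L
  else as.integer(bundle$config$end_age - bundle$config$start_age)
}

#' Run the Markov cohort model
#'
#' Propagates the initial occupancy through one transition matrix per year of
#' age, accruing costs and QALYs on start-of-cycle occupancy (no half-cycle
#' correction). Treatment costs accrue in treated states, the year-1 fracture
#' cost in the fracture tunnel, and the constant post-fracture annual cost
#' thereafter; utilities are the age-specific baseline, multiplied down in the
#' fracture and post-fracture states and zero when dead. The upfront
#' assessment cost enters at cycle 0. Both streams are discounted by
#' [discount_factor()].
#'
#' @param initial A [state_distribution()] (or a `screening_outcome`, whose
#'   distribution and upfront cost are then used).
#' @param bundle A validated [parameter_bundle()].
#' @param upfront_cost Money added at cycle 0 (ignored when `initial` is a
#'   `screening_outcome`).
#' @param matrices Optional pre-built list of transition matrices (one per
#'   cycle), as produced internally; used to avoid rebuilding across
#'   strategies that share a bundle.
#' @return An object of class `markov_trace`: list with `cycles` (data frame:
#'   cycle, age, cost, qaly, disc_cost, disc_qaly), `occupancy`
#'   (`(n_cycles + 1) x 9` matrix of start-of-cycle occupancy, final row is
#'   end-of-horizon), `cohort_size`, `upfront_cost`.
#' @export
run_cohort <- function(initial, bundle, upfront_cost = 0, matrices = NULL) {
  if (inherits(initial, "screening_outcome")) {
    upfront_cost <- initial$upfront_cost
    initial <- initial$distribution
  }
  validate_bundle(bundle)
  occ0 <- as.numeric(state_distribution(unclass(initial)))
  K <- n_model_cycles(bundle)
  if (K < 1) stop("horizon must cover at least one cycle", call. = FALSE)
  N <- sum(occ0)
  r <- bundle$config$discount_rate
  cvec <- state_cost_vector(bundle)

  occ <- matrix(0, K + 1, 9, dimnames = list(NULL, health_states()))
  occ[1, ] <- occ0
  cost <- qaly <- numeric(K)
  ages <- bundle$config$start_age + seq_len(K) - 1L
  for (k in seq_len(K)) {
    age <- ages[k]
    cur <- occ[k, ]
    cost[k] <- sum(cur * cvec) + if (k == 1) upfront_cost else 0
    qaly[k] <- sum(cur * state_utility_vector(bundle, age))
    P <- if (is.null(matrices)) build_transition_matrix(age, bundle)
         else matrices[[k]]
    nxt <- as.numeric(cur %*% P)
    if (abs(sum(nxt) - N) > 1e-6 * max(1, N))
      stop("occupancy not conserved at cycle ", k, call. = FALSE)
    occ[k + 1, ] <- nxt
  }
  disc <- discount_factor(r, seq_len(K) - 1L)
  structure(list(cycles = data.frame(cycle = seq_len(K) - 1L, age = ages,
                                     cost = cost, qaly = qaly,
                                     disc_cost = cost * disc,
                                     disc_qaly = qaly * disc),
                 occupancy = occ, cohort_size = N, upfront_cost = upfront_cost),
            class = "markov_trace")
}

#' @export
print.markov_trace <- function(x, ...) {
  cat(sprintf("<markov_trace> %d cycles, cohort %g\n", nrow(x$cycles), x$cohort_size))
  cat(sprintf("  total discounted cost %.2f, QALYs %.4f (cohort)\n",
              sum(x$cycles$disc_cost), sum(x$cycles$disc_qaly)))
  invisible(x)
}

#' Per-person totals of a Markov trace
#'
#' @param trace A [run_cohort()] result.
#' @return Object of class `strategy_outcome`: list with `mean_cost` and
#'   `mean_qaly`, the discounted per-person totals.
#' @export
trace_totals <- function(trace) {
  if (!inherits(trace, "markov_trace") || nrow(trace$cycles) == 0)
    stop("'trace' must be a non-empty markov_trace", call. = FALSE)
  structure(list(mean_cost = sum(trace$cycles$disc_cost) / trace$cohort_size,
                 mean_qaly = sum(trace$cycles$disc_qaly) / trace$cohort_size),
            class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> mean cost %.2f, mean QALYs %.4f per person\n",
              x$mean_cost, x$mean_qaly))
  invisible(x)
}

#' Tidy per-cycle trace export
#'
#' Long-format view of a trace: one row per cycle and state, with the cycle's
#' cost/QALY accruals and their discounted values attached.
#'
#' @param trace A [run_cohort()] result.
#' @return Data frame with columns cycle, age, state, occupancy, cost, qaly,
#'   disc_cost, disc_qaly.
#' @export
trace_to_df <- function(trace) {
  K <- nrow(trace$cycles)
  st <- health_states()
  data.frame(cycle = rep(trace$cycles$cycle, each = 9),
             age = rep(trace$cycles$age, each = 9),
             state = rep(st, K),
             occupancy = as.vector(t(trace$occupancy[seq_len(K), , drop = FALSE])),
             cost = rep(trace$cycles$cost, each = 9),
             qaly = rep(trace$cycles$qaly, each = 9),
             disc_cost = rep(trace$cycles$disc_cost, each = 9),
             disc_qaly = rep(trace$cycles$disc_qaly, each = 9))
}

#' Individual-level microsimulation oracle
#'
#' Monte-Carlo replica of [run_cohort()]: simulates individual annual
#' trajectories through the same transition rows with the same accrual rules,
#' returning mean discounted cost/QALY estimates with standard errors. Used
#' to validate the cohort expectation; agreement within Monte-Carlo error is a
#' structural check on the engine.
#'
#' @param initial A [state_distribution()] (persons; sampled proportionally).
#' @param bundle A validated [parameter_bundle()].
#' @param upfront_cost Cohort-level upfront cost, shared equally per person.
#' @param n_individuals Number of simulated persons (> 0).
#' @param seed Integer seed; the same seed gives identical estimates.
#' @return List with `mean_cost`, `mean_qaly`, `se_cost`, `se_qaly`, `n`.
#' @export
microsim_oracle <- function(initial, bundle, upfront_cost = 0,
                            n_individuals = 10000, seed = 1L) {
  if (inherits(initial, "screening_outcome")) {
    upfront_cost <- initial$upfront_cost
    initial <- initial$distribution
  }
  if (n_individuals <= 0) stop("'n_individuals' must be positive", call. = FALSE)
  validate_bundle(bundle)
  occ0 <- as.numeric(state_distribution(unclass(initial)))
  N <- sum(occ0)
  K <- n_model_cycles(bundle)
  r <- bundle$config$discount_rate
  cvec <- state_cost_vector(bundle)
  n <- as.integer(n_individuals)

  with_seed(seed, {
    state <- sample.int(9, n, replace = TRUE, prob = occ0 / N)
    cost_i <- rep(upfront_cost / N, n)
    qaly_i <- numeric(n)
    for (k in seq_len(K)) {
      age <- bundle$config$start_age + k - 1L
      d <- discount_factor(r, k - 1L)
      uvec <- state_utility_vector(bundle, age)
      cost_i <- cost_i + d * cvec[state]
      qaly_i <- qaly_i + d * uvec[state]
      cumP <- t(apply(build_transition_matrix(age, bundle), 1, cumsum))
      cumP[, 9] <- 1                               # guard rounding in the last column
      u <- stats::runif(n)
      state <- max.col(u <= cumP[state, , drop = FALSE], ties.method = "first")
    }
    list(mean_cost = mean(cost_i), mean_qaly = mean(qaly_i),
         se_cost = stats::sd(cost_i) / sqrt(n),
         se_qaly = stats::sd(qaly_i) / sqrt(n), n = n)
  })
}
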