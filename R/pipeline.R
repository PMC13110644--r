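#' Run one strategy end to end
#'
#' Screening cascade, Markov cohort run, and per-person totals for one
#' strategy under one bundle.
#'
#' @param bundle A validated [parameter_bundle()].
#' @param strategy_id `"S1"`, `"S2"` or `"S3"`.
#' @param matrices Optional pre-built transition matrices (shared across
#'   strategies of the same bundle).
#' @return List with `outcome` ([trace_totals()]), `trace`, `screening`.
#' @export
run_strategy <- function(bundle, strategy_id, matrices = NULL) {
  scr <- initial_state_distribution(strategy_id, bundle)
  trace <- run_cohort(scr$distribution, bundle, scr$upfront_cost,
                      matrices = matrices)
  list(outcome = trace_totals(trace), trace = trace, screening = scr)
}

build_all_matrices <- function(bundle) {
  K <- n_model_cycles(bundle)
  lapply(seq_len(K) - 1L,
         function(k) build_transition_matrix(bundle$config$start_age + k, bundle))
}

#' Run the full cost-effectiveness analysis
#'
#' Runs all three strategies under one bundle and compares them pairwise
#' against the comparator (plus S3 versus S2 when the comparator is S1).
#'
#' @param bundle A validated [parameter_bundle()].
#' @param comparator Comparator strategy id (default `"S1"`).
#' @param keep_traces Keep the per-strategy Markov traces (memory-heavier;
#'   disabled inside PSA loops).
#' @return Object of class `cea_result`: list with `outcomes` (named list of
#'   [trace_totals()]), `comparisons` ([compare_strategies()] table),
#'   `screening` (per-strategy cascade outcomes) and optionally `traces`.
#' @export
run_cea <- function(bundle, comparator = "S1", keep_traces = FALSE) {
  validate_bundle(bundle)
  mats <- build_all_matrices(bundle)
  runs <- lapply(c(S1 = "S1", S2 = "S2", S3 = "S3"),
                 function(id) run_strategy(bundle, id, matrices = mats))
  outcomes <- lapply(runs, `[[`, "outcome")
  res <- list(outcomes = outcomes,
              comparisons = compare_strategies(outcomes, comparator,
                                               bundle$config$thresholds),
              screening = lapply(runs, `[[`, "screening"))
  if (keep_traces) res$traces <- lapply(runs, `[[`, "trace")
  structure(res, class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  for (id in names(x$outcomes))
    cat(sprintf("  %s: mean cost %.2f, mean QALYs %.4f\n", id,
                x$outcomes[[id]]$mean_cost, x$outcomes[[id]]$mean_qaly))
  print(x$comparisons, digits = 4)
  invisible(x)
}

#' Cycle-1 occupancy check
#'
#' Model-verification report: the predicted number of persons in each health
#' state immediately after screening (cycle 0) and after the first annual
#' transition (cycle 1), per strategy. Occupancies sum to the cohort size.
#'
#' @param cea A [run_cea()] result with `keep_traces = TRUE`.
#' @return Data frame with columns strategy, cycle, state, persons.
#' @export
cycle1_occupancy <- function(cea) {
  if (is.null(cea$traces))
    stop("run_cea(..., keep_traces = TRUE) is required", call. = FALSE)
  st <- health_states()
  do.call(rbind, lapply(names(cea$traces), function(id) {
    occ <- cea$traces[[id]]$occupancy
    data.frame(strategy = id, cycle = rep(0:1, each = 9), state = rep(st, 2),
               persons = c(occ[1, ], occ[2, ]), stringsAsFactors = FALSE)
  }))
}
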