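#' Define a deterministic scenario
#'
#' A scenario changes exactly one parameter of a bundle: either setting it to
#' a value or multiplying it. The `path` is a character vector of list keys
#' into the bundle, e.g. `c("costs", "cost_dxa")` or
#' `c("screening", "S2", "sensitivity")`.
#'
#' @param label Human-readable scenario name.
#' @param path Character vector addressing the parameter in the bundle.
#' @param modifier `"set_value"` or `"multiply"`.
#' @param operand Numeric (or character for enum fields with `"set_value"`).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(label, path, modifier = c("set_value", "multiply"),
                          operand) {
  modifier <- match.arg(modifier)
  structure(list(label = label, path = path, modifier = modifier,
                 operand = operand), class = "scenario_spec")
}

#' Apply a scenario to a bundle
#'
#' Returns a modified copy; the input bundle is untouched. The modified bundle
#' is re-validated, so a change that breaks an invariant (e.g. a probability
#' above 1) errors rather than propagating.
#'
#' @param bundle A validated [parameter_bundle()].
#' @param scenario A [scenario_spec()].
#' @return A validated, modified [parameter_bundle()].
#' @export
apply_scenario <- function(bundle, scenario) {
  if (!inherits(scenario, "scenario_spec"))
    stop("'scenario' must be a scenario_spec", call. = FALSE)
  node <- bundle
  for (key in scenario$path) {
    if (!is.list(node) || is.null(node[[key]]))
      stop("unknown parameter path: ", paste(scenario$path, collapse = "$"),
           call. = FALSE)
    node <- node[[key]]
  }
  new <- switch(scenario$modifier,
                set_value = scenario$operand,
                multiply = node * scenario$operand)
  if (is.numeric(node) && is.numeric(new)) {
    # probability-type fields must stay in [0, 1]
    if (all(node >= 0 & node <= 1) && !all(new >= 0 & new <= 1) &&
        !grepl("cost|multiplier", utils::tail(scenario$path, 1)))
      stop("scenario '", scenario$label, "' pushes ",
           paste(scenario$path, collapse = "$"), " outside [0, 1]", call. = FALSE)
  }
  bundle[[scenario$path]] <- new
  validate_bundle(bundle)
  bundle
}

#' Built-in deterministic scenario grid
#'
#' The one-way scenarios of the deterministic sensitivity analysis: treatment
#' adherence at 80% of base and at 100%; each risk tool's sensitivity and
#' specificity at 80% of base and at the upper bound (100%, with 99.9% for
#' the IDFracture sensitivity); every unit cost halved and doubled; the
#' current-practice screened fraction at 1% and 5%; a 10-year time horizon;
#' and the linear lifetime fracture-risk extrapolation. The identity scenario
#' (`base_case`) is included first.
#'
#' @param bundle A validated [parameter_bundle()] (used for relative bounds).
#' @return List of [scenario_spec()].
#' @export
default_scenarios <- function(bundle) {
  sc <- list(scenario_spec("base_case", c("config", "cycle_length"),
                           "multiply", 1))
  add <- function(label, path, modifier, operand)
    sc[[length(sc) + 1]] <<- scenario_spec(label, path, modifier, operand)

  add("adherence_minus20pct", c("epidemiology", "adherence_annual"), "multiply", 0.8)
  add("adherence_100pct", c("epidemiology", "adherence_annual"), "set_value", 1.0)
  for (id in c("S1", "S2")) {
    tool <- bundle$screening[[id]]$tool
    add(paste0(tolower(tool), "_sensitivity_minus20pct"),
        c("screening", id, "sensitivity"), "multiply", 0.8)
    add(paste0(tolower(tool), "_sensitivity_max"),
        c("screening", id, "sensitivity"), "set_value",
        if (tool == "IDFracture") 0.999 else 1.0)
    add(paste0(tolower(tool), "_specificity_minus20pct"),
        c("screening", id, "specificity"), "multiply", 0.8)
    add(paste0(tolower(tool), "_specificity_100pct"),
        c("screening", id, "specificity"), "set_value", 1.0)
  }
  cost_fields <- c(risk_score = "cost_risk_score", dxa = "cost_dxa",
                   osteoporosis_treatment = "cost_treat_osteoporosis_annual",
                   osteopenia_treatment = "cost_treat_osteopenia_annual",
                   fracture = "cost_fracture_year1",
                   postfracture = "cost_postfracture_annual")
  for (nm in names(cost_fields)) {
    add(paste0(nm, "_cost_halved"), c("costs", cost_fields[[nm]]), "multiply", 0.5)
    add(paste0(nm, "_cost_doubled"), c("costs", cost_fields[[nm]]), "multiply", 2)
  }
  add("s1_screened_1pct", c("screening", "S1", "screened_fraction"), "set_value", 0.01)
  add("s1_screened_5pct", c("screening", "S1", "screened_fraction"), "set_value", 0.05)
  add("ten_year_horizon", c("config", "horizon_mode"), "set_value", "ten_year")
  add("lifetime_fracture_risk", c("config", "risk_scale"), "set_value", "lifetime")
  sc
}

#' One-way deterministic sensitivity analysis
#'
#' Runs the full pipeline (decision tree, Markov model, economics) once per
#' scenario and stacks the pairwise comparison tables.
#'
#' @param bundle A validated [parameter_bundle()].
#' @param scenarios List of [scenario_spec()]; defaults to
#'   [default_scenarios()].
#' @param comparator Comparator strategy id.
#' @return Data frame: the [compare_strategies()] columns preceded by a
#'   `scenario` label column.
#' @export
run_dsa <- function(bundle, scenarios = default_scenarios(bundle),
                    comparator = "S1") {
  if (!length(scenarios)) stop("'scenarios' must be non-empty", call. = FALSE)
  do.call(rbind, lapply(scenarios, function(sc) {
    res <- run_cea(apply_scenario(bundle, sc), comparator)
    cbind(scenario = sc$label, as.data.frame(res$comparisons))
  }))
}

# beta draw around a base probability; boundary values are structural zeros/ones
# and stay fixed
draw_prob <- function(x, cv) {
  fixed <- x <= 0 | x >= 1 | cv == 0
  out <- x
  if (any(!fixed)) {
    ab <- vapply(x[!fixed], function(m) beta_from_mean_cv(m, cv), numeric(2))
    out[!fixed] <- stats::rbeta(sum(!fixed), ab[1, ], ab[2, ])
  }
  out
}

draw_cost <- function(x, cv) {
  fixed <- x <= 0 | cv == 0
  out <- x
  if (any(!fixed)) {
    ss <- vapply(x[!fixed], function(m) gamma_from_mean_cv(m, cv), numeric(2))
    out[!fixed] <- stats::rgamma(sum(!fixed), shape = ss[1, ], scale = ss[2, ])
  }
  out
}

#' Draw one probabilistic-sensitivity-analysis bundle
#'
#' Replaces every probability and utility parameter by a moment-matched beta
#' draw and every unit cost by a moment-matched gamma draw, using the
#' per-group coefficients of variation stored in the bundle. Parameters are
#' sampled independently; baseline BMD prevalences are renormalised to sum to
#' 1 after sampling. Structural settings (discounting, horizon, cohort size)
#' and the mortality multipliers are never sampled, and parameters sitting
#' exactly on the boundary of their support (0 or 1, or zero cost) are kept
#' fixed.
#'
#' @param bundle A validated [parameter_bundle()] carrying CVs.
#' @param seed Optional integer seed (deterministic draw when given).
#' @return A validated, sampled [parameter_bundle()].
#' @export
draw_psa_bundle <- function(bundle, seed = NULL) {
  validate_bundle(bundle)
  cv <- bundle$uncertainty
  run <- function() {
    b <- bundle
    for (id in c("S1", "S2", "S3")) {
      p <- b$screening[[id]]
      p$screened_fraction <- draw_prob(p$screened_fraction, cv[["screening"]])
      p$sensitivity <- draw_prob(p$sensitivity, cv[["screening"]])
      p$specificity <- draw_prob(p$specificity, cv[["screening"]])
      b$screening[[id]] <- p
    }
    e <- b$epidemiology
    prev <- draw_prob(c(e$prev_osteoporosis, e$prev_osteopenia, e$prev_normal),
                      cv[["prevalence"]])
    prev <- prev / sum(prev)
    e$prev_osteoporosis <- prev[1]; e$prev_osteopenia <- prev[2]
    e$prev_normal <- prev[3]
    e$frac_no_fracture <- draw_prob(e$frac_no_fracture, cv[["prevalence"]])
    e$p10_fracture_by_state[] <- draw_prob(e$p10_fracture_by_state,
                                           cv[["fracture_risk"]])
    e$refracture_annual <- draw_prob(e$refracture_annual, cv[["fracture_risk"]])
    e$rr_bisphosphonate <- draw_prob(e$rr_bisphosphonate, cv[["treatment_effect"]])
    e$rr_vitd_calcium <- draw_prob(e$rr_vitd_calcium, cv[["treatment_effect"]])
    e$adherence_annual <- draw_prob(e$adherence_annual, cv[["adherence"]])
    e$background_mortality$prob <- draw_prob(e$background_mortality$prob,
                                             cv[["mortality"]])
    b$epidemiology <- e
    for (nm in names(b$costs))
      b$costs[[nm]] <- draw_cost(b$costs[[nm]], cv[["costs"]])
    u <- b$utilities
    u$baseline_utility_by_age$utility <- draw_prob(u$baseline_utility_by_age$utility,
                                                   cv[["utilities"]])
    u$fracture_year_multiplier <- draw_prob(u$fracture_year_multiplier,
                                            cv[["utilities"]])
    u$postfracture_multiplier <- draw_prob(u$postfracture_multiplier,
                                           cv[["utilities"]])
    b$utilities <- u
    validate_bundle(b)
    b
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Probabilistic sensitivity analysis
#'
#' Samples `n_draws` bundles with [draw_psa_bundle()], re-runs the full
#' pipeline (including the decision tree, so screening uncertainty
#' propagates) on each, and records the incremental cost/QALY point of every
#' pairwise comparison.
#'
#' @param bundle A validated [parameter_bundle()].
#' @param n_draws Number of draws (default 1000).
#' @param seed Integer seed driving the whole analysis.
#' @param comparator Comparator strategy id.
#' @return Object of class `psa_result`: list with `points` (data frame:
#'   draw, intervention, comparator, delta_cost, delta_qaly), `n_draws`,
#'   `seed`, `thresholds`.
#' @export
run_psa <- function(bundle, n_draws = 1000, seed = 1L, comparator = "S1") {
  if (n_draws < 1) stop("'n_draws' must be at least 1", call. = FALSE)
  validate_bundle(bundle)
  seeds <- derive_seeds(seed, n_draws)
  pts <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    res <- run_cea(draw_psa_bundle(bundle, seeds[i]), comparator)
    cmp <- res$comparisons
    pts[[i]] <- data.frame(draw = i, intervention = cmp$intervention,
                           comparator = cmp$comparator,
                           delta_cost = cmp$delta_cost,
                           delta_qaly = cmp$delta_qaly,
                           stringsAsFactors = FALSE)
  }
  structure(list(points = do.call(rbind, pts), n_draws = n_draws, seed = seed,
                 thresholds = bundle$config$thresholds),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %d), comparisons: %s\n", x$n_draws,
              x$seed, paste(unique(paste(x$points$intervention, "vs",
                                         x$points$comparator)), collapse = ", ")))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each comparison, `CEAC(lambda)` is the fraction of PSA draws with
#' strictly positive incremental net monetary benefit
#' `lambda * delta_qaly - delta_cost > 0`. Ties at exactly zero count as not
#' cost-effective.
#'
#' @param points A `psa_result` or its `points` data frame.
#' @param lambdas Non-empty grid of willingness-to-pay values.
#' @return Data frame: intervention, comparator, lambda, probability.
#' @export
compute_ceac <- function(points, lambdas = seq(0, 50000, by = 1000)) {
  if (inherits(points, "psa_result")) points <- points$points
  if (!length(lambdas)) stop("'lambdas' must be non-empty", call. = FALSE)
  if (!nrow(points)) stop("'points' must be non-empty", call. = FALSE)
  key <- paste(points$intervention, points$comparator, sep = ".")
  do.call(rbind, lapply(split(points, key), function(d) {
    data.frame(intervention = d$intervention[1], comparator = d$comparator[1],
               lambda = lambdas,
               probability = vapply(lambdas, function(l)
                 mean(l * d$delta_qaly - d$delta_cost > 0), numeric(1)),
               stringsAsFactors = FALSE)
  }))
}

#' Cost-effectiveness plane
#'
#' Scatter of PSA incremental cost/QALY points per comparison, with
#' willingness-to-pay rays at the bundle's thresholds.
#'
#' @param psa A [run_psa()] result.
#' @param thresholds Rays to draw (money per QALY).
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, thresholds = psa$thresholds) {
  pts <- psa$points
  pts$comparison <- paste(pts$intervention, "vs", pts$comparator)
  rays <- data.frame(slope = thresholds,
                     label = paste0("£", format(thresholds, big.mark = ",")))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_abline(data = rays,
                         ggplot2::aes(slope = .data$slope, intercept = 0,
                                      linetype = .data$label), colour = "grey40") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue") +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)",
                  linetype = "Threshold") +
    ggplot2::theme_minimal()
}

#' @rdname plot_ce_plane
#' @param ceac A [compute_ceac()] result (for `plot_ceac`).
#' @export
plot_ceac <- function(ceac) {
  ceac$comparison <- paste(ceac$intervention, "vs", ceac$comparator)
  ggplot2::ggplot(ceac, ggplot2::aes(x = .data$lambda, y = .data$probability,
                                     colour = .data$comparison)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (GBP per QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}
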