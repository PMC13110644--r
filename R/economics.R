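#' Dominance quadrant of an incremental comparison
#'
#' Maps an incremental cost/QALY pair onto the cost-effectiveness plane:
#' `dominant` (cheaper and more effective), `dominated` (costlier and less
#' effective), `trade_off_NE` (north-east: more costly, more effective) or
#' `trade_off_SW`. Exact zeros are assigned deterministically: any pair with
#' `delta_qaly >= 0` that is not strictly dominant falls in the NE quadrant,
#' otherwise SW.
#'
#' @param delta_cost Incremental cost.
#' @param delta_qaly Incremental QALYs.
#' @return One of `"dominant"`, `"dominated"`, `"trade_off_NE"`,
#'   `"trade_off_SW"`.
#' @export
classify_dominance <- function(delta_cost, delta_qaly) {
  if (delta_cost < 0 && delta_qaly > 0) "dominant"
  else if (delta_cost > 0 && delta_qaly < 0) "dominated"
  else if (delta_qaly >= 0) "trade_off_NE"
  else "trade_off_SW"
}

#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_qaly`, tagged with its dominance quadrant. A negative
#' ICER on its own is ambiguous (it arises in both the dominant and the
#' dominated quadrant), so the quadrant label always accompanies the number.
#' When `delta_qaly` is exactly 0 the ratio is undefined and a labelled
#' non-numeric result is returned rather than an error.
#'
#' @param delta_cost Incremental cost.
#' @param delta_qaly Incremental QALYs.
#' @return Object of class `icer_result`: list with `value` (numeric, `NA`
#'   when undefined), `defined` (logical), `dominance`, `label`.
#' @examples
#' icer(-7.23, 0.0028)  # dominant, about -2582 per QALY
#' @export
icer <- function(delta_cost, delta_qaly) {
  dom <- classify_dominance(delta_cost, delta_qaly)
  if (delta_qaly == 0) {
    structure(list(value = NA_real_, defined = FALSE, dominance = dom,
                   label = "undefined (delta QALY = 0)"),
              class = "icer_result")
  } else {
    v <- delta_cost / delta_qaly
    structure(list(value = v, defined = TRUE, dominance = dom,
                   label = sprintf("%.1f (%s)", v, dom)),
              class = "icer_result")
  }
}

#' @export
print.icer_result <- function(x, ...) {
  cat("<icer> ", x$label, "\n", sep = "")
  invisible(x)
}

#' Incremental net monetary benefit
#'
#' `threshold * delta_qaly - delta_cost`. Positive at a threshold means the
#' intervention is cost-effective versus its comparator at that
#' willingness-to-pay.
#'
#' @param delta_cost Incremental cost.
#' @param delta_qaly Incremental QALYs.
#' @param threshold Willingness-to-pay (money per QALY, >= 0); vectorised.
#' @return Money (same length as `threshold`).
#' @examples
#' nmb(-7.23, 0.0028, 15000)  # 49.23
#' @export
nmb <- function(delta_cost, delta_qaly, threshold) {
  if (any(threshold < 0)) stop("'threshold' must be non-negative", call. = FALSE)
  threshold * delta_qaly - delta_cost
}

#' Pairwise incremental comparisons between strategies
#'
#' Compares every non-comparator strategy against the comparator, and — when
#' both S2 and S3 are present with S1 as comparator — additionally S3 against
#' S2. Each row carries the intervention's mean cost/QALYs, the incremental
#' values, the ICER with its dominance label, and the incremental net
#' monetary benefit at each threshold (columns `nmb_<threshold>`).
#'
#' @param outcomes Named list of [trace_totals()] results (or any list with
#'   `mean_cost`, `mean_qaly`), keyed by strategy id.
#' @param comparator_id Strategy id used as the comparator (default `"S1"`).
#' @param thresholds Willingness-to-pay thresholds.
#' @return Data frame of class `pairwise_comparison` with one row per
#'   comparison.
#' @export
compare_strategies <- function(outcomes, comparator_id = "S1",
                               thresholds = c(15000, 20000, 30000)) {
  if (!comparator_id %in% names(outcomes))
    stop("comparator '", comparator_id, "' missing from outcomes", call. = FALSE)
  others <- setdiff(names(outcomes), comparator_id)
  if (!length(others)) stop("need at least one non-comparator strategy", call. = FALSE)
  pairs <- lapply(others, function(id) c(id, comparator_id))
  if (comparator_id == "S1" && all(c("S2", "S3") %in% names(outcomes)))
    pairs <- c(pairs, list(c("S3", "S2")))

  rows <- lapply(pairs, function(p) {
    iv <- outcomes[[p[1]]]; cp <- outcomes[[p[2]]]
    dc <- iv$mean_cost - cp$mean_cost
    de <- iv$mean_qaly - cp$mean_qaly
    ic <- icer(dc, de)
    row <- data.frame(intervention = p[1], comparator = p[2],
                      mean_cost = iv$mean_cost, mean_qaly = iv$mean_qaly,
                      delta_cost = dc, delta_qaly = de,
                      icer = ic$value, dominance = ic$dominance,
                      stringsAsFactors = FALSE)
    for (lam in thresholds)
      row[[paste0("nmb_", format(lam, scientific = FALSE))]] <- nmb(dc, de, lam)
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pairwise_comparison", class(out))
  out
}

#' Base-case comparison table
#'
#' Table-shaped summary: one row per strategy (comparator first, with empty
#' incremental cells), in the column order mean cost, mean QALY, incremental
#' cost, incremental QALY, ICER and NMB per threshold.
#'
#' @inheritParams compare_strategies
#' @return Data frame with one row per strategy.
#' @export
comparison_table <- function(outcomes, comparator_id = "S1",
                             thresholds = c(15000, 20000, 30000)) {
  cmp <- compare_strategies(outcomes, comparator_id, thresholds)
  cmp <- cmp[cmp$comparator == comparator_id, ]
  base <- data.frame(strategy = comparator_id,
                     mean_cost = outcomes[[comparator_id]]$mean_cost,
                     mean_qaly = outcomes[[comparator_id]]$mean_qaly,
                     delta_cost = NA_real_, delta_qaly = NA_real_,
                     icer = NA_real_, dominance = NA_character_,
                     stringsAsFactors = FALSE)
  for (lam in thresholds)
    base[[paste0("nmb_", format(lam, scientific = FALSE))]] <- NA_real_
  rest <- cmp[, setdiff(names(cmp), "comparator")]
  names(rest)[names(rest) == "intervention"] <- "strategy"
  rbind(base, rest)
}
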