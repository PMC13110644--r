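# Reporting commands: each writes CSV outputs plus a JSON run manifest into
# out_dir and never mutates its inputs. Monetary columns are GBP at 2021/22
# prices; every CSV carries that note as a leading '#' comment line.

price_note <- "# costs in GBP, 2021/22 prices"

write_report_csv <- function(df, path, note = price_note) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(note, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read back a report CSV
#'
#' @param path CSV written by one of the `report_*` functions.
#' @return Data frame (the leading comment line is skipped).
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

write_manifest <- function(out_dir, command, bundle, seed = NULL, extra = list()) {
  man <- c(list(command = command,
                package = "osteocea",
                version = as.character(utils::packageVersion("osteocea")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                fracture_type = bundle$config$fracture_type,
                cohort_size = bundle$config$cohort_size,
                seed = seed,
                bundle_hash = digest_bundle(bundle)),
           extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(man)
}

# order-stable fingerprint of the numeric content of a bundle
digest_bundle <- function(bundle) {
  nums <- unlist(rapply(unclass(bundle),
                        function(v) if (is.numeric(v)) v else NULL,
                        how = "unlist"))
  sprintf("%.10e:%.10e", sum(nums), sum(nums * nums))
}

#' Base-case report
#'
#' Writes the base-case comparison table (`base_case.csv`, one strategy per
#' row in Table-1 column order) and the cycle-1 occupancy model check
#' (`cycle1_occupancy.csv`), plus a run manifest.
#'
#' @param bundle A validated [parameter_bundle()].
#' @param out_dir Output directory (created if missing).
#' @param comparator Comparator strategy id.
#' @return The [run_cea()] result, invisibly.
#' @export
report_base_case <- function(bundle, out_dir, comparator = "S1") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_cea(bundle, comparator, keep_traces = TRUE)
  tab <- comparison_table(res$outcomes, comparator, bundle$config$thresholds)
  write_report_csv(tab, file.path(out_dir, "base_case.csv"))
  write_report_csv(cycle1_occupancy(res),
                   file.path(out_dir, "cycle1_occupancy.csv"),
                   note = "# model check: persons per health state after screening")
  write_manifest(out_dir, "base-case", bundle)
  invisible(res)
}

#' Probabilistic sensitivity analysis report
#'
#' Writes the cost-effectiveness plane point cloud (`ce_plane.csv`), the
#' acceptability curves (`ceac.csv`) and a manifest recording the seed.
#'
#' @param bundle A validated [parameter_bundle()].
#' @param out_dir Output directory.
#' @param n_draws Number of PSA draws (default 1000).
#' @param seed Integer seed.
#' @param comparator Comparator strategy id.
#' @param lambdas Willingness-to-pay grid for the CEAC.
#' @return The [run_psa()] result, invisibly.
#' @export
report_psa <- function(bundle, out_dir, n_draws = 1000, seed = 1L,
                       comparator = "S1", lambdas = seq(0, 50000, by = 1000)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(bundle, n_draws = n_draws, seed = seed, comparator = comparator)
  write_report_csv(psa$points, file.path(out_dir, "ce_plane.csv"))
  write_report_csv(compute_ceac(psa, lambdas), file.path(out_dir, "ceac.csv"),
                   note = "# probability of positive incremental net monetary benefit")
  write_manifest(out_dir, "psa", bundle, seed = seed,
                 extra = list(n_draws = n_draws))
  invisible(psa)
}

#' Deterministic sensitivity analysis report
#'
#' Writes the per-scenario comparison table (`dsa.csv`) and a manifest.
#'
#' @inheritParams report_base_case
#' @param scenarios List of [scenario_spec()]; defaults to
#'   [default_scenarios()].
#' @return The [run_dsa()] table, invisibly.
#' @export
report_dsa <- function(bundle, out_dir, scenarios = default_scenarios(bundle),
                       comparator = "S1") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- run_dsa(bundle, scenarios, comparator)
  write_report_csv(tab, file.path(out_dir, "dsa.csv"))
  write_manifest(out_dir, "dsa", bundle,
                 extra = list(n_scenarios = length(scenarios)))
  invisible(tab)
}

#' Subgroup analysis report
#'
#' Writes the per-subgroup comparison table (`subgroups.csv`) and a manifest.
#'
#' @inheritParams report_base_case
#' @param specs List of subgroup specs; defaults to
#'   [default_subgroup_specs()].
#' @return The [run_subgroups()] table, invisibly.
#' @export
report_subgroups <- function(bundle, out_dir, specs = default_subgroup_specs(),
                             comparator = "S1") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- run_subgroups(bundle, specs, comparator)
  write_report_csv(tab, file.path(out_dir, "subgroups.csv"))
  write_manifest(out_dir, "subgroups", bundle,
                 extra = list(n_subgroups = length(specs)))
  invisible(tab)
}
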