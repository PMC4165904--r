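# Reporting: formatted results tables, machine-readable writers and run
# manifests.  Machine outputs carry JPY as plain numbers; the USD column
# (fixed conversion, 100 JPY = 1 USD) is display-only.

jpy_per_usd <- 100

#' Formatted base-case results table
#'
#' The per-arm cost and QALY components with differences, in the layout of
#' the published base-case table; optionally with a display-only USD column
#' at the fixed 100 JPY = 1 USD conversion.
#'
#' @param result A `cea_result` from [cea_run()].
#' @param usd Add a USD column for cost rows.
#' @return A tibble `metric`, `without_assay`, `with_assay`, `difference`
#'   (and `difference_usd` when `usd = TRUE`).
#' @export
cea_table <- function(result, usd = FALSE) {
  tab <- tidy(result)
  if (usd) {
    tab$difference_usd <- ifelse(grepl("^cost", tab$metric),
                                 tab$difference / jpy_per_usd, NA_real_)
  }
  tab
}

#' Run manifest
#'
#' A reproducibility record written beside every machine output: hash of the
#' resolved inputs, risk source, settings snapshot, package version,
#' timestamp and seed.  Two runs with identical manifests (timestamp aside)
#' produce identical outputs.
#'
#' @param inputs A `cea_inputs` object.
#' @param seed Seed used for any stochastic step, or `NULL`.
#' @export
run_manifest <- function(inputs, seed = NULL) {
  list(
    input_hash = rlang::hash(list(inputs$groups, inputs$risk_sources,
                                  inputs$costs, inputs$utilities,
                                  inputs$settings, inputs$life_table)),
    risk_source = inputs$settings$risk_source,
    settings = inputs$settings,
    package_version = as.character(utils::packageVersion("assaycea")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed
  )
}

#' Write cost-effectiveness results to disk
#'
#' Writes `results.csv` (one row per metric, per-arm values and difference),
#' `results.json` (per-arm records plus the incremental record), and
#' `manifest.json`.
#'
#' @param result A `cea_result`.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest, if any.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cea_results <- function(result, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(dir, "results.csv")
  json_path <- file.path(dir, "results.json")
  manifest_path <- file.path(dir, "manifest.json")
  readr::write_csv(tidy(result), csv_path)
  payload <- list(
    arms = as.data.frame(result$arms),
    incremental = as.list(as.data.frame(result$incremental)),
    risk_source = result$inputs$settings$risk_source
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(run_manifest(result$inputs, seed), manifest_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path, manifest = manifest_path))
}
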