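# One-way (tornado) sensitivity analysis, the alternative risk-source
# scenario, and the chemotherapy-drug-cost break-even threshold.

icer_or_flag <- function(result) {
  inc <- result$incremental
  # For tornado ordering the cost/QALY ratio is kept even under dominance
  # (negative when the assay is cost-saving); the flag records dominance.
  ratio <- if (inc$delta_qaly != 0) inc$delta_cost / inc$delta_qaly
           else NA_real_
  list(icer = ratio, dominance = inc$dominance)
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs the full model twice per parameter, once at its low and once at
#' its high sensitivity bound, with all other inputs held at base.  Rows are
#' sorted by descending swing, `|icer_at_high - icer_at_low|`.  When a bound
#' makes the assay strategy dominant (cost-saving and QALY-gaining) the
#' cost/QALY ratio is negative; it is still reported, so the swing stays
#' orderable as on published tornado diagrams, and the dominance column
#' records the flag.  A bound that produces an invalid model is flagged in
#' `status` and the run continues.
#'
#' @param inputs A `cea_inputs` object.
#' @param parameters Optional tibble `id`, `base`, `low`, `high` (defaults
#'   to [sensitivity_parameters()]).
#' @return A `cea_tornado` tibble: `parameter`, `low_value`, `high_value`,
#'   `icer_at_low`, `icer_at_high`, `dominance_at_low`, `dominance_at_high`,
#'   `swing`, `status`; attribute `base_icer` carries the base-case ICER.
#' @examples
#' \donttest{
#' torn <- one_way_sensitivity(default_inputs())
#' head(torn, 3)
#' }
#' @export
one_way_sensitivity <- function(inputs, parameters = NULL) {
  validate_inputs(inputs)
  if (is.null(parameters)) parameters <- sensitivity_parameters(inputs)
  base_icer <- cea_run(inputs)$incremental$icer

  eval_at <- function(id, value) {
    tryCatch({
      res <- cea_run(set_parameter(inputs, id, value))
      c(icer_or_flag(res), list(status = "ok"))
    }, error = function(e) {
      list(icer = NA_real_, dominance = NA_character_, status = "invalid")
    })
  }

  rows <- purrr::pmap_dfr(parameters, function(id, base, low, high) {
    lo <- eval_at(id, low)
    hi <- eval_at(id, high)
    status <- if (lo$status == "ok" && hi$status == "ok") "ok" else "invalid"
    swing <- if (status == "ok" && !is.na(lo$icer) && !is.na(hi$icer)) {
      abs(hi$icer - lo$icer)
    } else NA_real_
    tibble::tibble(parameter = id, low_value = low, high_value = high,
                   icer_at_low = lo$icer, icer_at_high = hi$icer,
                   dominance_at_low = lo$dominance,
                   dominance_at_high = hi$dominance,
                   swing = swing, status = status)
  })
  out <- dplyr::arrange(rows, dplyr::desc(.data$swing))
  attr(out, "base_icer") <- base_icer
  class(out) <- c("cea_tornado", class(out))
  out
}

#' Alternative-scenario analysis with US/UK baseline recurrence risks
#'
#' Swaps in the baseline 10-year distant recurrence risks estimated by the
#' US- and UK-based validation studies and re-runs the full analysis.  The
#' acute-cost differences are unchanged (they do not depend on recurrence
#' risk).
#'
#' @param inputs A `cea_inputs` object.
#' @return A `cea_result`.
#' @export
run_alternative_scenario <- function(inputs) {
  cea_run(set_risk_source(inputs, "us_uk"))
}

#' Break-even chemotherapy drug cost
#'
#' Bisects on the chemotherapy drug cost until the lifetime cost difference
#' between the two arms vanishes (|delta cost| below `tol`); above the
#' returned cost the assay strategy is cost-saving.  All other inputs stay
#' at base.
#'
#' @param inputs A `cea_inputs` object.
#' @param bracket Search interval for the drug cost, JPY.
#' @param tol Absolute tolerance on the cost difference, JPY.
#' @return The break-even drug cost (JPY), with attribute `delta_cost`
#'   giving the residual; `NA` (with a message) if the cost difference does
#'   not change sign over the bracket.
#' @examples
#' \donttest{
#' threshold_chemo_cost(default_inputs())
#' }
#' @export
threshold_chemo_cost <- function(inputs, bracket = c(0, 1e7), tol = 1) {
  delta_at <- function(drug_cost) {
    cea_run(set_parameter(inputs, "cost.chemo_drugs",
                          drug_cost))$incremental$delta_cost
  }
  f_lo <- delta_at(bracket[1])
  f_hi <- delta_at(bracket[2])
  if (sign(f_lo) == sign(f_hi)) {
    message("delta cost does not change sign over the bracket; no break-even threshold")
    return(NA_real_)
  }
  lo <- bracket[1]; hi <- bracket[2]
  mid <- (lo + hi) / 2
  repeat {
    f_mid <- delta_at(mid)
    if (abs(f_mid) < tol || (hi - lo) < 1e-6) break
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
    mid <- (lo + hi) / 2
  }
  structure(mid, delta_cost = delta_at(mid))
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' Horizontal bars from the ICER at each parameter's low bound to the ICER
#' at its high bound, largest swing on top, with a reference line at the
#' base-case ICER.
#'
#' @param object A `cea_tornado` tibble from [one_way_sensitivity()].
#' @param top_n Number of parameters to show (by swing).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cea_tornado
#' @export
autoplot.cea_tornado <- function(object, top_n = 12, ...) {
  base_icer <- attr(object, "base_icer")
  dat <- object |>
    dplyr::filter(!is.na(.data$swing), .data$swing > 0) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(parameter = factor(.data$parameter,
                                     levels = rev(.data$parameter)))
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$icer_at_low, xend = .data$icer_at_high,
      y = .data$parameter, yend = .data$parameter),
      linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = "dashed") +
    ggplot2::labs(x = "ICER (JPY per QALY gained)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cea_tornado
#' @param tornado A `cea_tornado` tibble.
#' @export
plot_tornado <- function(tornado, top_n = 12) {
  autoplot.cea_tornado(tornado, top_n = top_n)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a tornado table to CSV
#'
#' Columns `parameter,low_value,high_value,icer_at_low,icer_at_high,swing`,
#' sorted by descending swing.
#'
#' @param tornado A `cea_tornado` tibble.
#' @param path Output CSV path.
#' @export
write_tornado <- function(tornado, path) {
  readr::write_csv(
    tornado[, c("parameter", "low_value", "high_value", "icer_at_low",
                "icer_at_high", "swing")], path)
  invisible(path)
}
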