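# Discounted cost and QALY accounting, strategy evaluation and the ICER.
#
# Acute chemotherapy costs and the chemotherapy QALY tariff are time-zero
# lump sums and are not discounted.  Lifetime flows (utility-weighted
# occupancy, surveillance cost while recurrence-free, post-recurrence cost)
# are discounted per cycle; with the half-cycle correction on, occupancy is
# the mean of cycle-start and cycle-end mass and the discount factor is
# evaluated at mid-cycle.

cost_base <- function(costs, item) costs$base[match(item, costs$item)]
utility_base <- function(utilities, item) {
  utilities$base[match(item, utilities$item)]
}

#' Acute (time-zero) chemotherapy-related costs per average patient
#'
#' Each component is the unit cost multiplied by the proportion of the
#' cohort receiving adjuvant chemotherapy; no discounting applies.
#'
#' @param chemo_proportion Proportion receiving chemotherapy.
#' @param costs The `costs` tibble of a `cea_inputs` object.
#' @return A one-row tibble: `drugs`, `adverse_events`, `time_transport` (JPY).
#' @examples
#' acute_costs(48 / 104, default_inputs()$costs)
#' @export
acute_costs <- function(chemo_proportion, costs) {
  stopifnot(chemo_proportion >= 0, chemo_proportion <= 1)
  tibble::tibble(
    drugs = cost_base(costs, "chemo_drugs") * chemo_proportion,
    adverse_events = cost_base(costs, "adverse_events") * chemo_proportion,
    time_transport = cost_base(costs, "time_transport") * chemo_proportion
  )
}

#' Immediate QALY loss from adjuvant chemotherapy
#'
#' The one-time QALY tariff of undergoing chemotherapy, applied at time zero
#' (undiscounted) to the treated fraction of the cohort.
#'
#' @param chemo_proportion Proportion receiving chemotherapy.
#' @param tariff QALYs lost per treated patient.
#' @return A non-positive number of QALYs.
#' @export
immediate_chemo_qaly_loss <- function(chemo_proportion, tariff) {
  stopifnot(chemo_proportion >= 0, tariff >= 0)
  -tariff * chemo_proportion
}

#' Discounted lifetime outcomes of one cohort trace
#'
#' Accrues, cycle by cycle: utility-weighted QALYs (recurrence-free utility
#' times recurrence-free occupancy plus progression utility times
#' distant-recurrence occupancy), surveillance cost while recurrence-free,
#' and post-recurrence cost while alive after distant recurrence.  Cycle `k`
#' is discounted by `(1 + rate)^-(k + h)` with `h = 0.5` under the
#' half-cycle correction (occupancy then being the mean of cycle-start and
#' cycle-end mass) and `h = 0` otherwise (cycle-start occupancy).
#'
#' @param trace A `cohort_trace` tibble.
#' @param costs,utilities,settings Components of a `cea_inputs` object.
#' @return A one-row tibble: `qaly_long_term`, `cost_monitoring`,
#'   `cost_recurrence`.
#' @export
lifetime_outcomes <- function(trace, costs, utilities, settings) {
  n <- nrow(trace) - 1L
  if (n < 1L) {
    return(tibble::tibble(qaly_long_term = 0, cost_monitoring = 0,
                          cost_recurrence = 0))
  }
  rf <- trace$recurrence_free
  rec <- trace$distant_recurrence
  hcc <- isTRUE(settings$half_cycle_correction)
  if (hcc) {
    w_rf <- (rf[1:n] + rf[2:(n + 1L)]) / 2
    w_rec <- (rec[1:n] + rec[2:(n + 1L)]) / 2
    h <- 0.5
  } else {
    w_rf <- rf[1:n]
    w_rec <- rec[1:n]
    h <- 0
  }
  df <- (1 + settings$discount_rate)^-(seq_len(n) - 1 + h)
  u_rf <- utility_base(utilities, "u_recurrence_free")
  u_prog <- utility_base(utilities, "u_progression")
  tibble::tibble(
    qaly_long_term = sum((w_rf * u_rf + w_rec * u_prog) * df),
    cost_monitoring = sum(w_rf * df) * cost_base(costs, "surveillance_annual"),
    cost_recurrence = sum(w_rec * df) * cost_base(costs, "recurrence_annual")
  )
}

subgroup_trace <- function(inputs, label, treated) {
  g <- inputs$groups[inputs$groups$label == label, ]
  s <- inputs$settings
  risk10 <- chemo_adjusted_risk(g$baseline_risk_10y, g$rrr_chemo, treated)
  horizon <- if (s$recurrence_hazard_mode == "lifetime") Inf else 10
  spec <- subgroup_spec(label, treated,
                        annual_prob_from_cumulative(risk10, 10),
                        horizon, s$start_age)
  run_subgroup_cohort(spec, as.numeric(treated), inputs)
}

#' Evaluate one strategy arm
#'
#' Runs six subgroup cohorts (three risk groups, chemotherapy yes/no),
#' weights them by cohort share and the arm's chemotherapy recommendation
#' rates, and assembles the per-average-patient discounted cost and QALY
#' components plus the 10-year recurrence-free survival (all deaths and
#' recurrences count as events).
#'
#' @param inputs A `cea_inputs` object.
#' @param arm `"without_assay"` (pre-assay chemotherapy rates) or
#'   `"with_assay"` (post-assay rates plus the assay cost).
#' @return A one-row `strategy_result` tibble with the chemotherapy
#'   proportion, 10-year recurrence-free survival, QALY components and the
#'   six cost components plus totals (JPY, discounted).
#' @examples
#' evaluate_strategy(default_inputs(), "without_assay")
#' @export
evaluate_strategy <- function(inputs, arm = c("without_assay", "with_assay")) {
  arm <- match.arg(arm)
  g <- inputs$groups
  rates <- if (arm == "without_assay") g$chemo_rate_pre else g$chemo_rate_post
  chemo_prop <- sum(g$cohort_share * rates)

  cells <- tidyr::expand_grid(label = g$label, treated = c(TRUE, FALSE)) |>
    dplyr::mutate(
      share = g$cohort_share[match(.data$label, g$label)],
      rate = rates[match(.data$label, g$label)],
      weight = .data$share * ifelse(.data$treated, .data$rate, 1 - .data$rate)
    ) |>
    dplyr::filter(.data$weight > 0)

  acc <- purrr::pmap_dfr(cells, function(label, treated, share, rate, weight) {
    trace <- subgroup_trace(inputs, label, treated)
    lt <- lifetime_outcomes(trace, inputs$costs, inputs$utilities,
                            inputs$settings)
    rfs <- if (any(trace$cycle == 10)) {
      trace$recurrence_free[trace$cycle == 10]
    } else 0
    tibble::tibble(weight = weight,
                   qaly_long_term = lt$qaly_long_term,
                   cost_monitoring = lt$cost_monitoring,
                   cost_recurrence = lt$cost_recurrence,
                   rfs_10y = rfs)
  })
  w <- acc$weight
  qaly_long_term <- sum(w * acc$qaly_long_term)
  cost_monitoring <- sum(w * acc$cost_monitoring)
  cost_recurrence <- sum(w * acc$cost_recurrence)
  rfs_10y <- sum(w * acc$rfs_10y)

  ac <- acute_costs(chemo_prop, inputs$costs)
  qaly_imm <- immediate_chemo_qaly_loss(
    chemo_prop, utility_base(inputs$utilities, "chemo_qaly_tariff"))
  cost_assay <- if (arm == "with_assay") cost_base(inputs$costs, "assay") else 0

  out <- tibble::tibble(
    arm = arm,
    chemo_proportion = chemo_prop,
    rfs_10y = rfs_10y,
    qaly_immediate_chemo = qaly_imm,
    qaly_long_term = qaly_long_term,
    qaly_total = qaly_imm + qaly_long_term,
    cost_assay = cost_assay,
    cost_chemo_drugs = ac$drugs,
    cost_adverse_events = ac$adverse_events,
    cost_time_transport = ac$time_transport,
    cost_monitoring = cost_monitoring,
    cost_recurrence = cost_recurrence
  )
  out$cost_total <- out$cost_assay + out$cost_chemo_drugs +
    out$cost_adverse_events + out$cost_time_transport +
    out$cost_monitoring + out$cost_recurrence
  class(out) <- c("strategy_result", class(out))
  out
}

#' Incremental comparison of two strategy results
#'
#' Cost and QALY differences (intervention minus base) and the incremental
#' cost-effectiveness ratio computed on unrounded values.  Dominance is
#' flagged instead of an ICER when the intervention is cheaper and more
#' effective (`dominant`) or dearer and less effective (`dominated`); a zero
#' QALY difference yields an undefined ICER, not an error.
#'
#' @param base,intervention One-row `strategy_result` tibbles from the same
#'   inputs.
#' @return A one-row `cea_incremental` tibble: `delta_cost`, `delta_qaly`,
#'   `icer`, `dominance`.
#' @export
incremental <- function(base, intervention) {
  delta_cost <- intervention$cost_total - base$cost_total
  delta_qaly <- intervention$qaly_total - base$qaly_total
  dominance <- NA_character_
  icer <- NA_real_
  if (delta_cost < 0 && delta_qaly > 0) {
    dominance <- "dominant"
  } else if (delta_cost > 0 && delta_qaly < 0) {
    dominance <- "dominated"
  } else if (delta_qaly != 0) {
    icer <- delta_cost / delta_qaly
  }
  out <- tibble::tibble(delta_cost = delta_cost, delta_qaly = delta_qaly,
                        icer = icer, dominance = dominance)
  class(out) <- c("cea_incremental", class(out))
  out
}

#' Run the full cost-effectiveness analysis
#'
#' Evaluates both strategy arms and their incremental comparison.
#'
#' @param inputs A `cea_inputs` object (see [default_inputs()]).
#' @return A `cea_result` object: list with `arms` (two stacked
#'   `strategy_result` rows), `incremental`, and the `inputs` used.
#' @examples
#' res <- cea_run(default_inputs())
#' glance(res)
#' @export
cea_run <- function(inputs) {
  validate_inputs(inputs)
  without <- evaluate_strategy(inputs, "without_assay")
  with_ <- evaluate_strategy(inputs, "with_assay")
  structure(
    list(arms = dplyr::bind_rows(without, with_),
         incremental = incremental(without, with_),
         inputs = inputs),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  inc <- x$incremental
  cat("Cost-effectiveness analysis (risk source:",
      x$inputs$settings$risk_source, ")\n")
  print(tidy(x), n = 20)
  cat(sprintf("\n  delta cost: %s JPY   delta QALY: %.4f\n",
              format(round(inc$delta_cost), big.mark = ","), inc$delta_qaly))
  if (!is.na(inc$dominance)) {
    cat("  ", inc$dominance, "\n")
  } else if (is.na(inc$icer)) {
    cat("  ICER undefined (zero QALY difference)\n")
  } else {
    cat(sprintf("  ICER: %s JPY per QALY gained\n",
                format(round(inc$icer), big.mark = ",")))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cea_result into a long per-metric table
#'
#' One row per reported metric with a value per arm and the difference,
#' mirroring the base-case results table of the analysis.
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @method tidy cea_result
#' @export
tidy.cea_result <- function(x, ...) {
  metrics <- c("chemo_proportion", "rfs_10y", "qaly_immediate_chemo",
               "qaly_long_term", "qaly_total", "cost_assay",
               "cost_chemo_drugs", "cost_adverse_events",
               "cost_time_transport", "cost_monitoring", "cost_recurrence",
               "cost_total")
  arms <- x$arms
  tibble::tibble(
    metric = metrics,
    without_assay = unname(unlist(arms[arms$arm == "without_assay", metrics])),
    with_assay = unname(unlist(arms[arms$arm == "with_assay", metrics]))
  ) |>
    dplyr::mutate(difference = .data$with_assay - .data$without_assay)
}

#' One-row summary of a cea_result
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @method glance cea_result
#' @export
glance.cea_result <- function(x, ...) {
  inc <- x$incremental
  arms <- x$arms
  tibble::tibble(
    risk_source = x$inputs$settings$risk_source,
    chemo_proportion_change =
      arms$chemo_proportion[2] - arms$chemo_proportion[1],
    delta_cost = inc$delta_cost,
    delta_qaly = inc$delta_qaly,
    icer = inc$icer,
    dominance = inc$dominance
  )
}
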