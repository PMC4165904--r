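# Synthetic-data generation and the individual-level microsimulation
# oracle used to validate the deterministic cohort engine.

#' Simulate a patient-level decision-impact table
#'
#' Emulates the structure of the decision-impact study: each patient is
#' assigned a recurrence-score risk group, then a pre-assay and a post-assay
#' chemotherapy recommendation drawn from that group's rates.
#'
#' @param inputs A `cea_inputs` object supplying group shares and pre/post
#'   recommendation rates.
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; runs with the same seed are bit-reproducible.
#' @return A tibble `patient_id`, `risk_group`, `rec_pre`, `rec_post`
#'   (logical recommendations).
#' @examples
#' tab <- simulate_decision_impact(default_inputs(), 104, seed = 1)
#' aggregate_decision_impact(tab)
#' @export
simulate_decision_impact <- function(inputs, n_patients = 104, seed = 1) {
  g <- inputs$groups
  stopifnot(abs(sum(g$cohort_share) - 1) < 1e-9, n_patients >= 1)
  set.seed(seed)
  grp_idx <- findInterval(stats::runif(n_patients),
                          cumsum(g$cohort_share), left.open = TRUE) + 1L
  grp_idx[grp_idx > nrow(g)] <- nrow(g)
  tibble::tibble(
    patient_id = seq_len(n_patients),
    risk_group = g$label[grp_idx],
    rec_pre = stats::runif(n_patients) < g$chemo_rate_pre[grp_idx],
    rec_post = stats::runif(n_patients) < g$chemo_rate_post[grp_idx]
  )
}

#' Aggregate a patient-level decision-impact table
#'
#' Recovers the per-group and overall counts and empirical recommendation
#' rates, in the layout of the published decision-impact table.
#'
#' @param table Output of [simulate_decision_impact()] (or any tibble with
#'   `risk_group`, `rec_pre`, `rec_post`).
#' @return A tibble with one row per risk group plus an `all` row: `n`,
#'   `n_pre`, `n_post`, `rate_pre`, `rate_post`, `change`.
#' @export
aggregate_decision_impact <- function(table) {
  per_group <- table |>
    dplyr::group_by(risk_group = factor(.data$risk_group,
                                        levels = risk_group_labels)) |>
    dplyr::summarise(n = dplyr::n(), n_pre = sum(.data$rec_pre),
                     n_post = sum(.data$rec_post), .groups = "drop") |>
    dplyr::mutate(risk_group = as.character(.data$risk_group))
  all_row <- tibble::tibble(risk_group = "all", n = nrow(table),
                            n_pre = sum(table$rec_pre),
                            n_post = sum(table$rec_post))
  dplyr::bind_rows(per_group, all_row) |>
    dplyr::mutate(rate_pre = .data$n_pre / .data$n,
                  rate_post = .data$n_post / .data$n,
                  change = .data$rate_post - .data$rate_pre)
}

#' Rebuild model inputs from an (empirical) decision-impact table
#'
#' Replaces the group sizes and pre/post recommendation rates of an input
#' bundle with the empirical values of a patient-level table, leaving risks,
#' costs, utilities and settings untouched.  Used for parameter-recovery
#' checks: a large synthetic table fed back through the pipeline should
#' reproduce the base-case results up to sampling error in the rates.
#'
#' @param table Patient-level table as from [simulate_decision_impact()].
#' @param inputs The `cea_inputs` bundle whose group rows are replaced.
#' @export
inputs_from_decision_impact <- function(table, inputs) {
  agg <- aggregate_decision_impact(table)
  agg <- agg[match(inputs$groups$label, agg$risk_group), ]
  if (any(is.na(agg$n)) || any(agg$n == 0)) {
    rlang::abort("decision-impact table must contain every risk group",
                 class = "cea_validation_error")
  }
  inputs$groups$n_patients <- agg$n
  inputs$groups$n_chemo_pre <- agg$n_pre
  inputs$groups$n_chemo_post <- agg$n_post
  inputs$groups$cohort_share <- agg$n / sum(agg$n)
  inputs$groups$chemo_rate_pre <- agg$rate_pre
  inputs$groups$chemo_rate_post <- agg$rate_post
  validate_inputs(inputs)
  inputs
}

#' Generate a parametric life table
#'
#' `gompertz`: annual death probability `q(age) = 1 - exp(-a * exp(b * age))`;
#' `flat`: constant `q`.  Probabilities above 1 are clamped with a warning.
#'
#' @param model `"gompertz"` or `"flat"`.
#' @param a,b Gompertz level and shape (both positive).
#' @param q Constant annual probability for the flat model.
#' @param max_age Last tabulated age.
#' @return A life-table tibble (`age`, `q_annual`).
#' @examples
#' synthetic_life_table("gompertz", a = 1e-5, b = 0.09)
#' @export
synthetic_life_table <- function(model = c("gompertz", "flat"), a = 1e-5,
                                 b = 0.09, q = 0.01, max_age = 110) {
  model <- match.arg(model)
  ages <- 0:max_age
  qv <- switch(model,
    gompertz = {
      stopifnot(a > 0, b > 0)
      1 - exp(-a * exp(b * ages))
    },
    flat = {
      stopifnot(q >= 0, q <= 1)
      rep(q, length(ages))
    }
  )
  if (any(qv > 1)) {
    rlang::warn("some annual death probabilities exceed 1; clamping")
    qv <- pmin(qv, 1)
  }
  tibble::tibble(age = ages, q_annual = qv)
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n_patients` one by one through the same annual transition
#' probabilities, discounting and accrual rules as the cohort engine, but by
#' Bernoulli sampling instead of expectation propagation.  Used as an
#' independent stochastic check of [evaluate_strategy()]: every cohort-model
#' component should sit within a few standard errors of the microsimulation
#' mean.
#'
#' Rewards follow the engine's half-cycle convention: each cycle accrues the
#' average of the utility (or state cost) at cycle start and cycle end,
#' discounted at mid-cycle.  Draws are consumed in a fixed cycle-major
#' order, so results for a given seed are bit-reproducible.
#'
#' @param inputs A `cea_inputs` object.
#' @param arm `"without_assay"` or `"with_assay"`.
#' @param n_patients Number of simulated patients (use 1000+ for meaningful
#'   standard errors).
#' @param seed Integer seed.
#' @return A `microsim_estimate` tibble: one row per metric (`qaly_total`,
#'   `qaly_immediate_chemo`, `qaly_long_term`, each cost component,
#'   `cost_total`, `rfs_10y`) with columns `mean`, `se`, and attributes
#'   `n_patients` and `seed`.
#' @examples
#' \donttest{
#' microsim(default_inputs(), "without_assay", n_patients = 2000, seed = 1)
#' }
#' @export
microsim <- function(inputs, arm = c("without_assay", "with_assay"),
                     n_patients = 10000, seed = 1) {
  arm <- match.arg(arm)
  validate_inputs(inputs)
  g <- inputs$groups
  s <- inputs$settings
  lt <- inputs$life_table
  rates <- if (arm == "without_assay") g$chemo_rate_pre else g$chemo_rate_post
  set.seed(seed)

  n <- as.integer(n_patients)
  grp <- findInterval(stats::runif(n), cumsum(g$cohort_share),
                      left.open = TRUE) + 1L
  grp[grp > nrow(g)] <- nrow(g)
  treated <- stats::runif(n) < rates[grp]
  tox_dead <- treated & (stats::runif(n) < s$fatal_toxicity_risk)

  # per-patient annual recurrence probability by (group, treated)
  risk10 <- chemo_adjusted_risk(g$baseline_risk_10y[grp], g$rrr_chemo[grp],
                                treated)
  p_rec <- annual_prob_from_cumulative(risk10, 10)
  horizon <- if (s$recurrence_hazard_mode == "lifetime") Inf else 10

  u_rf <- utility_base(inputs$utilities, "u_recurrence_free")
  u_prog <- utility_base(inputs$utilities, "u_progression")
  c_surv <- cost_base(inputs$costs, "surveillance_annual")
  c_rec <- cost_base(inputs$costs, "recurrence_annual")
  hcc <- isTRUE(s$half_cycle_correction)
  h <- if (hcc) 0.5 else 0

  # states: 1 RF, 2 recurrence, 3 dead (either cause); cause split only
  # matters for reporting, which the oracle does not do
  state <- ifelse(tox_dead, 3L, 1L)
  qaly_lt <- numeric(n)
  c_mon <- numeric(n)
  c_recur <- numeric(n)
  rfs10 <- rep(NA, n)
  max_cycles <- ceiling(s$max_age - s$start_age)

  state_u <- function(st) c(u_rf, u_prog, 0)[st]
  state_cmon <- function(st) c(c_surv, 0, 0)[st]
  state_crec <- function(st) c(0, c_rec, 0)[st]

  for (k in 0:(max_cycles - 1L)) {
    if (k == 10L) rfs10 <- state == 1L
    if (all(state == 3L)) {
      if (k <= 10L) rfs10 <- state == 1L
      break
    }
    age <- s$start_age + k
    q <- life_table_q(lt, age)
    p1 <- if (k < horizon) p_rec else rep(0, n)
    # competing-risk split on the rate scale, per patient
    r1 <- prob_to_rate(p1)
    r2 <- prob_to_rate(q)
    rt <- r1 + r2
    pe <- -expm1(-rt)
    to_rec <- ifelse(rt > 0, pe * r1 / rt, 0)
    to_dead_rf <- ifelse(rt > 0, pe * r2 / rt, 0)
    rb <- prob_to_rate(s$post_recurrence_mortality)
    rtd <- rb + r2
    ped <- -expm1(-rtd)
    to_dead_rec <- if (rtd > 0) ped else 0

    u <- stats::runif(n)
    new_state <- state
    rf <- which(state == 1L)
    p_r <- to_rec[rf]
    p_d <- p_r + to_dead_rf[rf]
    new_state[rf[u[rf] < p_r]] <- 2L
    new_state[rf[u[rf] >= p_r & u[rf] < p_d]] <- 3L
    rc <- which(state == 2L)
    new_state[rc[u[rc] < to_dead_rec]] <- 3L

    df <- (1 + s$discount_rate)^-(k + h)
    if (hcc) {
      qaly_lt <- qaly_lt + 0.5 * (state_u(state) + state_u(new_state)) * df
      c_mon <- c_mon + 0.5 * (state_cmon(state) + state_cmon(new_state)) * df
      c_recur <- c_recur +
        0.5 * (state_crec(state) + state_crec(new_state)) * df
    } else {
      qaly_lt <- qaly_lt + state_u(state) * df
      c_mon <- c_mon + state_cmon(state) * df
      c_recur <- c_recur + state_crec(state) * df
    }
    state <- new_state
  }
  if (anyNA(rfs10)) rfs10 <- state == 1L  # horizon shorter than 10 cycles

  tariff <- utility_base(inputs$utilities, "chemo_qaly_tariff")
  qaly_imm <- -tariff * treated
  cost_drugs <- cost_base(inputs$costs, "chemo_drugs") * treated
  cost_ae <- cost_base(inputs$costs, "adverse_events") * treated
  cost_tt <- cost_base(inputs$costs, "time_transport") * treated
  cost_assay <- rep(if (arm == "with_assay")
    cost_base(inputs$costs, "assay") else 0, n)
  cost_total <- cost_assay + cost_drugs + cost_ae + cost_tt + c_mon + c_recur

  metrics <- list(
    qaly_total = qaly_imm + qaly_lt,
    qaly_immediate_chemo = qaly_imm,
    qaly_long_term = qaly_lt,
    cost_assay = cost_assay,
    cost_chemo_drugs = cost_drugs,
    cost_adverse_events = cost_ae,
    cost_time_transport = cost_tt,
    cost_monitoring = c_mon,
    cost_recurrence = c_recur,
    cost_total = cost_total,
    rfs_10y = as.numeric(rfs10)
  )
  out <- purrr::imap_dfr(metrics, function(v, nm) {
    tibble::tibble(metric = nm, mean = mean(v),
                   se = stats::sd(v) / sqrt(n))
  })
  attr(out, "n_patients") <- n
  attr(out, "seed") <- seed
  attr(out, "arm") <- arm
  class(out) <- c("microsim_estimate", class(out))
  out
}
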