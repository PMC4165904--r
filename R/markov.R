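# Cohort state-transition engine.
#
# Four states: recurrence-free on study, distant recurrence, breast-cancer
# death (including fatal chemotherapy toxicity), other-cause death.  Annual
# cycles.  Competing risks within a cycle are combined on the rate scale and
# apportioned proportionally to the cause-specific rates, which keeps every
# transition row a valid probability vector even at extreme sensitivity
# bounds.

#' Convert a cumulative risk to a per-cycle probability
#'
#' Constant-hazard bridge: the annual probability whose compounding over
#' `horizon_years` reproduces the stated cumulative risk,
#' `1 - (1 - cum_risk)^(1 / horizon_years)`.
#'
#' @param cum_risk Cumulative event risk over the horizon, in \[0, 1).
#' @param horizon_years Positive horizon length in years.
#' @return Annual event probability (vectorised over `cum_risk`).
#' @examples
#' annual_prob_from_cumulative(0.248, 10)
#' @export
annual_prob_from_cumulative <- function(cum_risk, horizon_years) {
  if (any(horizon_years <= 0)) {
    rlang::abort("horizon_years must be positive", class = "cea_domain_error")
  }
  if (any(cum_risk < 0 | cum_risk >= 1)) {
    rlang::abort("cum_risk must lie in [0, 1): a cumulative risk of 1 implies infinite hazard",
                 class = "cea_domain_error")
  }
  1 - (1 - cum_risk)^(1 / horizon_years)
}

#' Chemotherapy-adjusted 10-year recurrence risk
#'
#' Applies the group's relative risk reduction when the patient is treated
#' with adjuvant chemotherapy; untreated patients keep the baseline risk.
#'
#' @param baseline_risk_10y Baseline 10-year distant recurrence risk.
#' @param rrr Relative risk reduction of recurrence with chemotherapy.
#' @param treated Logical; `TRUE` for chemotherapy-treated patients.
#' @export
chemo_adjusted_risk <- function(baseline_risk_10y, rrr, treated) {
  stopifnot(all(baseline_risk_10y >= 0 & baseline_risk_10y <= 1),
            all(rrr >= 0 & rrr <= 1))
  ifelse(treated, baseline_risk_10y * (1 - rrr), baseline_risk_10y)
}

prob_to_rate <- function(p) -log1p(-p)

# Two competing causes with annual probabilities p1, p2: total event
# probability 1 - exp(-(r1 + r2)) split r1 : r2.
competing_split <- function(p1, p2) {
  r1 <- prob_to_rate(p1)
  r2 <- prob_to_rate(p2)
  rt <- r1 + r2
  if (rt == 0) return(c(0, 0))
  if (is.infinite(rt)) {
    # at least one certain event; split by rate dominance
    w1 <- if (is.infinite(r1) && is.infinite(r2)) 0.5
          else as.numeric(is.infinite(r1))
    return(c(w1, 1 - w1))
  }
  p_event <- -expm1(-rt)
  c(p_event * r1 / rt, p_event * r2 / rt)
}

#' Subgroup specification for the cohort engine
#'
#' @param label Risk-group label.
#' @param chemo_treated Logical; whether this subgroup received adjuvant
#'   chemotherapy.
#' @param annual_recurrence_prob Annual probability of distant recurrence
#'   while the recurrence hazard is active.
#' @param recurrence_active_horizon Years after start during which the
#'   recurrence hazard applies (`Inf` for lifetime).
#' @param start_age Age at model start (surgery), years.
#' @export
subgroup_spec <- function(label, chemo_treated, annual_recurrence_prob,
                          recurrence_active_horizon = Inf, start_age = 49.8) {
  stopifnot(annual_recurrence_prob >= 0, annual_recurrence_prob < 1)
  structure(list(label = label, chemo_treated = chemo_treated,
                 annual_recurrence_prob = annual_recurrence_prob,
                 recurrence_active_horizon = recurrence_active_horizon,
                 start_age = start_age),
            class = "subgroup_spec")
}

#' Transition probabilities out of the recurrence-free state
#'
#' Distant recurrence competes with other-cause (life-table) death on the
#' rate scale; the remainder stays recurrence-free.  Past the recurrence
#' horizon the recurrence rate is zero.
#'
#' @param age Attained age at cycle start.
#' @param spec A [subgroup_spec()].
#' @param life_table Life-table tibble.
#' @param settings Model settings list.
#' @return Named probability vector over the four states (sums to 1).
#' @export
transition_row_recurrence_free <- function(age, spec, life_table, settings) {
  years_in <- age - spec$start_age
  p_rec <- if (years_in < spec$recurrence_active_horizon)
    spec$annual_recurrence_prob else 0
  q <- life_table_q(life_table, age)
  split <- competing_split(p_rec, q)
  out <- c(1 - sum(split), split[1], 0, split[2])
  names(out) <- cea_states
  out
}

#' Transition probabilities out of the distant-recurrence state
#'
#' Breast-cancer death after progression (annual probability
#' `post_recurrence_mortality`) competes with other-cause death on the rate
#' scale; the remainder stays in distant recurrence.
#'
#' @inheritParams transition_row_recurrence_free
#' @export
transition_row_recurrence <- function(age, settings, life_table) {
  q <- life_table_q(life_table, age)
  split <- competing_split(settings$post_recurrence_mortality, q)
  out <- c(0, 1 - sum(split), split[1], split[2])
  names(out) <- cea_states
  out
}

#' Initial occupancy after time-zero events
#'
#' A fraction `chemo_rate * fatal_toxicity_risk` of the cohort dies of
#' chemotherapy toxicity at time zero (counted as breast-cancer death); the
#' rest starts recurrence-free.
#'
#' @param chemo_rate Proportion of the cohort receiving chemotherapy.
#' @param settings Model settings list.
#' @export
apply_time_zero_events <- function(chemo_rate, settings) {
  stopifnot(chemo_rate >= 0, chemo_rate <= 1)
  d <- chemo_rate * settings$fatal_toxicity_risk
  out <- c(1 - d, 0, d, 0)
  names(out) <- cea_states
  out
}

#' Run one subgroup cohort to extinction
#'
#' Iterates annual cycles from the starting age until the living mass falls
#' below 1e-12 or the maximum age is reached, recording state occupancy at
#' every cycle start.  Fully deterministic.
#'
#' @param spec A [subgroup_spec()].
#' @param chemo_rate_context Chemotherapy proportion used for the time-zero
#'   fatal-toxicity event (1 for a fully treated subgroup, 0 untreated).
#' @param inputs A `cea_inputs` object.
#' @return A `cohort_trace` tibble: `cycle`, `age`, and one occupancy column
#'   per state; row `cycle = k` is the occupancy at the start of cycle `k`,
#'   after time-zero events.
#' @examples
#' inp <- default_inputs()
#' sg <- subgroup_spec("high", TRUE, 0.0066, Inf, 49.8)
#' trace <- run_subgroup_cohort(sg, 1, inp)
#' @export
run_subgroup_cohort <- function(spec, chemo_rate_context, inputs) {
  settings <- inputs$settings
  lt <- inputs$life_table
  max_cycles <- ceiling(settings$max_age - spec$start_age)
  occ <- matrix(NA_real_, nrow = max_cycles + 1L, ncol = 4L,
                dimnames = list(NULL, cea_states))
  occ[1L, ] <- apply_time_zero_events(chemo_rate_context, settings)
  k <- 0L
  while (k < max_cycles) {
    row <- occ[k + 1L, ]
    alive <- row[1L] + row[2L]
    if (alive < 1e-12) break
    age <- spec$start_age + k
    tr_rf <- transition_row_recurrence_free(age, spec, lt, settings)
    tr_rec <- transition_row_recurrence(age, settings, lt)
    nxt <- row[1L] * tr_rf + row[2L] * tr_rec
    nxt[3L] <- nxt[3L] + row[3L]
    nxt[4L] <- nxt[4L] + row[4L]
    occ[k + 2L, ] <- nxt
    k <- k + 1L
  }
  occ <- occ[seq_len(k + 1L), , drop = FALSE]
  out <- tibble::tibble(cycle = 0:k, age = spec$start_age + 0:k,
                        recurrence_free = occ[, 1L],
                        distant_recurrence = occ[, 2L],
                        dead_bc = occ[, 3L],
                        dead_other = occ[, 4L])
  class(out) <- c("cohort_trace", class(out))
  out
}

#' Write a cohort trace to CSV
#'
#' One row per cycle: `cycle,age,recurrence_free,distant_recurrence,dead_bc,dead_other`.
#'
#' @param trace A `cohort_trace` tibble.
#' @param path Output CSV path.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(trace, path)
  invisible(path)
}
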