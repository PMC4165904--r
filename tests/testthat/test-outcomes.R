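test_that("acute costs scale unit costs by the chemotherapy proportion", {
  costs <- base_inputs()$costs
  ac_pre <- acute_costs(48 / 104, costs)
  expect_equal(round(ac_pre$drugs), 259298)
  ac_post <- acute_costs(28 / 104, costs)
  expect_equal(round(ac_post$adverse_events), 45993)
  ac0 <- acute_costs(0, costs)
  expect_equal(unlist(ac0), c(drugs = 0, adverse_events = 0,
                              time_transport = 0))
})

test_that("immediate chemotherapy QALY loss is an undiscounted lump sum", {
  expect_equal(immediate_chemo_qaly_loss(48 / 104, 0.53), -0.53 * 48 / 104)
  expect_equal(immediate_chemo_qaly_loss(0, 0.53), 0)
  expect_equal(immediate_chemo_qaly_loss(1, 0.53), -0.53)
})

test_that("lifetime outcomes match hand-rolled discounted dot products", {
  inp <- base_inputs()

  # annuity limit: no discounting, no events, utility 1, 10 cycles
  flat_trace <- tibble::tibble(cycle = 0:10, age = 50 + 0:10,
                               recurrence_free = 1, distant_recurrence = 0,
                               dead_bc = 0, dead_other = 0)
  u1 <- inp$utilities; u1$base[u1$item == "u_recurrence_free"] <- 1
  s0 <- inp$settings; s0$discount_rate <- 0
  lt0 <- lifetime_outcomes(flat_trace, inp$costs, u1, s0)
  expect_equal(lt0$qaly_long_term, 10)
  expect_equal(lt0$cost_monitoring, 10 * 25416)

  # one full cohort-year in recurrence accrues one annual recurrence cost
  rec_trace <- tibble::tibble(cycle = 0:1, age = c(50, 51),
                              recurrence_free = 0,
                              distant_recurrence = c(1, 0),
                              dead_bc = c(0, 1), dead_other = 0)
  s_nohcc <- s0; s_nohcc$half_cycle_correction <- FALSE
  expect_equal(lifetime_outcomes(rec_trace, inp$costs, inp$utilities,
                                 s_nohcc)$cost_recurrence, 2405924)

  # real trace at 3%: independent dot product over the trace columns
  tr <- subgroup_trace_for_test(inp, "high", FALSE)
  got <- lifetime_outcomes(tr, inp$costs, inp$utilities, inp$settings)
  n <- nrow(tr) - 1
  w_rf <- (tr$recurrence_free[1:n] + tr$recurrence_free[2:(n + 1)]) / 2
  w_rec <- (tr$distant_recurrence[1:n] + tr$distant_recurrence[2:(n + 1)]) / 2
  df <- 1.03^-(0:(n - 1) + 0.5)
  expect_equal(got$qaly_long_term, sum((0.98 * w_rf + 0.30 * w_rec) * df),
               tolerance = 1e-12)
  expect_equal(got$cost_monitoring, 25416 * sum(w_rf * df), tolerance = 1e-9)
  expect_equal(got$cost_recurrence, 2405924 * sum(w_rec * df),
               tolerance = 1e-9)

  # without the half-cycle correction, cycle-start occupancy is used
  s_plain <- inp$settings; s_plain$half_cycle_correction <- FALSE
  got2 <- lifetime_outcomes(tr, inp$costs, inp$utilities, s_plain)
  df2 <- 1.03^-(0:(n - 1))
  expect_equal(got2$qaly_long_term,
               sum((0.98 * tr$recurrence_free[1:n] +
                    0.30 * tr$distant_recurrence[1:n]) * df2),
               tolerance = 1e-12)
})

test_that("strategy results are internally consistent", {
  res <- evaluate_strategy(base_inputs(), "without_assay")
  expect_equal(res$cost_total,
               res$cost_assay + res$cost_chemo_drugs +
                 res$cost_adverse_events + res$cost_time_transport +
                 res$cost_monitoring + res$cost_recurrence,
               tolerance = 0.5)
  expect_equal(res$qaly_total, res$qaly_immediate_chemo + res$qaly_long_term,
               tolerance = 1e-9)
  expect_equal(res$chemo_proportion, 48 / 104, tolerance = 1e-12)
})

test_that("an assay arm with pre-assay rates and free assay is the comparator", {
  inp <- set_parameter(base_inputs(), "cost.assay", 0)
  inp$groups$chemo_rate_post <- inp$groups$chemo_rate_pre
  inp$groups$n_chemo_post <- inp$groups$n_chemo_pre
  a <- evaluate_strategy(inp, "without_assay")
  b <- evaluate_strategy(inp, "with_assay")
  expect_equal(as.data.frame(a[, -1]), as.data.frame(b[, -1]),
               tolerance = 1e-12)
})

test_that("incremental comparison handles ICERs and dominance", {
  mk <- function(cost, qaly) {
    tibble::tibble(cost_total = cost, qaly_total = qaly)
  }
  inc <- incremental(mk(0, 0), mk(1e5, 0.5))
  expect_equal(inc$icer, 2e5)
  expect_true(is.na(inc$dominance))

  dom <- incremental(mk(1, 0), mk(0, 1))
  expect_equal(dom$dominance, "dominant")
  expect_true(is.na(dom$icer))

  ded <- incremental(mk(0, 1), mk(1, 0))
  expect_equal(ded$dominance, "dominated")

  flat <- incremental(mk(0, 1), mk(5, 1))
  expect_true(is.na(flat$icer))
  expect_true(is.na(flat$dominance))
})

test_that("acute-cost differences between arms are exact to the yen", {
  res <- cea_run(base_inputs())
  tab <- tidy(res)
  d <- function(m) tab$difference[tab$metric == m]
  expect_equal(d("cost_chemo_drugs"), -561813 * 20 / 104, tolerance = 1e-9)
  expect_equal(d("cost_adverse_events"), -170831 * 20 / 104, tolerance = 1e-9)
  expect_equal(d("cost_time_transport"), -68500 * 20 / 104, tolerance = 1e-9)
  expect_equal(round(-(d("cost_chemo_drugs") + d("cost_adverse_events") +
                         d("cost_time_transport"))), 154066)
})

test_that("removing discounting increases every positive lifetime flow", {
  inp <- base_inputs()
  r3 <- evaluate_strategy(inp, "without_assay")
  r0 <- evaluate_strategy(set_parameter(inp, "settings.discount_rate", 0),
                          "without_assay")
  expect_gt(r0$qaly_long_term, r3$qaly_long_term)
  expect_gt(r0$cost_monitoring, r3$cost_monitoring)
  expect_gt(r0$cost_recurrence, r3$cost_recurrence)
})

test_that("ICER falls as chemotherapy drugs get dearer, until cost-saving", {
  inp <- base_inputs()
  ratio_at <- function(cost) {
    inc <- cea_run(set_parameter(inp, "cost.chemo_drugs", cost))$incremental
    inc$delta_cost / inc$delta_qaly
  }
  ratios <- vapply(c(280907, 561813, 1000000, 1360000, 1500000), ratio_at,
                   numeric(1))
  expect_true(all(diff(ratios) < 0))
  expect_lt(ratios[5], 0)  # beyond break-even the assay is cost-saving
})

test_that("tidy and glance summarise a cea_result", {
  res <- cea_run(base_inputs())
  tab <- tidy(res)
  expect_equal(nrow(tab), 12)
  expect_equal(names(tab), c("metric", "without_assay", "with_assay",
                             "difference"))
  g <- glance(res)
  expect_equal(g$chemo_proportion_change, -20 / 104, tolerance = 1e-12)
  expect_equal(g$icer, res$incremental$icer)
})

test_that("modelling conventions rank as documented: hazard mode dominates", {
  inp <- base_inputs()
  icer_base <- cea_run(inp)$incremental$icer

  inp10 <- inp; inp10$settings$recurrence_hazard_mode <- "first_10_years"
  r10 <- cea_run(inp10)
  # confining the recurrence hazard to ten years guts the post-recurrence
  # cost stream and inflates the ICER by tens of percent
  expect_lt(tidy(r10)$without_assay[tidy(r10)$metric == "cost_recurrence"],
            0.5 * tidy(cea_run(inp))$without_assay[
              tidy(cea_run(inp))$metric == "cost_recurrence"])
  expect_gt(r10$incremental$icer, 1.3 * icer_base)

  # the half-cycle convention is second-order (both discount at mid-cycle)
  inp_h <- inp; inp_h$settings$half_cycle_correction <- FALSE
  expect_lt(abs(cea_run(inp_h)$incremental$icer - icer_base),
            0.01 * icer_base)

  # removing fatal toxicity shifts the ICER by only a few percent
  inp_t <- inp
  inp_t$settings$fatal_toxicity_risk <- 0
  inp_t$settings$fatal_toxicity_low <- 0
  expect_lt(abs(cea_run(inp_t)$incremental$icer - icer_base),
            0.05 * icer_base)
})
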