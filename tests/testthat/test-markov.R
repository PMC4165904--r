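test_that("constant-hazard bridge converts cumulative to annual risk", {
  expect_equal(annual_prob_from_cumulative(0, 10), 0)
  # closed form 1 - (1 - 0.248)^(1/10), the high-risk 10-year risk
  expect_equal(annual_prob_from_cumulative(0.248, 10), 1 - 0.752^0.1,
               tolerance = 1e-12)
  expect_equal(annual_prob_from_cumulative(0.248, 10), 0.02810,
               tolerance = 1e-4)
  expect_equal(annual_prob_from_cumulative(0.033, 10), 1 - 0.967^0.1,
               tolerance = 1e-12)
  expect_equal(annual_prob_from_cumulative(0.033, 10), 0.003350,
               tolerance = 1e-4)

  # inverse property: compounding the annual probability over the horizon
  # reproduces the cumulative risk
  for (cum in c(0.01, 0.137, 0.248, 0.6, 0.95)) {
    p <- annual_prob_from_cumulative(cum, 10)
    expect_equal(1 - (1 - p)^10, cum, tolerance = 1e-12)
  }

  expect_error(annual_prob_from_cumulative(1, 10), "hazard",
               class = "cea_domain_error")
  expect_error(annual_prob_from_cumulative(0.2, 0), "positive",
               class = "cea_domain_error")
})

test_that("chemotherapy adjustment multiplies risk by one minus the RRR", {
  expect_equal(chemo_adjusted_risk(0.248, 0.74, TRUE), 0.248 * 0.26)
  expect_equal(chemo_adjusted_risk(0.033, 0.0, TRUE), 0.033)
  expect_equal(chemo_adjusted_risk(0.137, 0.39, FALSE), 0.137)
})

test_that("recurrence-free transition row is a competing-risk split", {
  inp <- base_inputs()
  s <- inp$settings
  sg <- function(p) subgroup_spec("x", FALSE, p, Inf, 50)
  lt_q <- function(q) tibble::tibble(age = 0, q_annual = q)

  row0 <- transition_row_recurrence_free(55, sg(0), lt_q(0), s)
  expect_equal(unname(row0), c(1, 0, 0, 0))

  row1 <- transition_row_recurrence_free(55, sg(0), lt_q(0.01), s)
  expect_equal(row1[["dead_other"]], 0.01)
  expect_equal(row1[["recurrence_free"]], 0.99)

  # two active risks: total event probability is the independent product
  # complement, apportioned by cause-specific rates
  p1 <- 0.0281; q <- 0.002
  row2 <- transition_row_recurrence_free(55, sg(p1), lt_q(q), s)
  expect_equal(sum(row2), 1, tolerance = 1e-12)
  p_event <- 1 - (1 - p1) * (1 - q)
  r1 <- -log(1 - p1); r2 <- -log(1 - q)
  expect_equal(row2[["distant_recurrence"]], p_event * r1 / (r1 + r2),
               tolerance = 1e-12)
  expect_equal(row2[["dead_other"]], p_event * r2 / (r1 + r2),
               tolerance = 1e-12)

  # past the recurrence horizon the recurrence rate is zero
  sg10 <- subgroup_spec("x", FALSE, p1, 10, 50)
  row3 <- transition_row_recurrence_free(61, sg10, lt_q(q), s)
  expect_equal(row3[["distant_recurrence"]], 0)
})

test_that("post-recurrence transition row competes the two death causes", {
  inp <- base_inputs()
  s <- inp$settings
  lt_q <- function(q) tibble::tibble(age = 0, q_annual = q)

  row <- transition_row_recurrence(55, s, lt_q(0))
  expect_equal(row[["dead_bc"]], 0.40)
  expect_equal(row[["distant_recurrence"]], 0.60)

  s0 <- s; s0$post_recurrence_mortality <- 0
  expect_equal(transition_row_recurrence(55, s0, lt_q(0))[["distant_recurrence"]], 1)

  row2 <- transition_row_recurrence(55, s, lt_q(0.01))
  expect_equal(row2[["dead_bc"]] + row2[["dead_other"]],
               1 - 0.6 * 0.99, tolerance = 1e-12)
})

test_that("time-zero events move fatal-toxicity deaths out of the cohort", {
  s <- base_inputs()$settings
  row <- apply_time_zero_events(48 / 104, s)
  expect_equal(row[["dead_bc"]], 48 / 104 * 0.002, tolerance = 1e-12)
  expect_equal(sum(row), 1)
  expect_equal(unname(apply_time_zero_events(0, s)), c(1, 0, 0, 0))
  s0 <- s; s0$fatal_toxicity_risk <- 0
  expect_equal(unname(apply_time_zero_events(1, s0)), c(1, 0, 0, 0))
})

test_that("cohort trace matches a hand-rolled matrix-product oracle", {
  inp <- base_inputs()
  sg <- subgroup_spec("high", FALSE, annual_prob_from_cumulative(0.248, 10),
                      Inf, 49.8)
  trace <- run_subgroup_cohort(sg, 0, inp)

  # independent 4x4 chain built from closed-form competing-risk entries
  occ <- c(1, 0, 0, 0)
  for (k in 0:9) {
    age <- 49.8 + k
    q <- inp$life_table$q_annual[findInterval(floor(age), inp$life_table$age)]
    p1 <- sg$annual_recurrence_prob
    r1 <- -log(1 - p1); r2 <- -log(1 - q)
    pe_rf <- 1 - (1 - p1) * (1 - q)
    rb <- -log(1 - 0.40)
    pe_rec <- 1 - 0.60 * (1 - q)
    M <- rbind(
      c(1 - pe_rf, pe_rf * r1 / (r1 + r2), 0, pe_rf * r2 / (r1 + r2)),
      c(0, 1 - pe_rec, pe_rec * rb / (rb + r2), pe_rec * r2 / (rb + r2)),
      c(0, 0, 1, 0),
      c(0, 0, 0, 1))
    occ <- as.numeric(occ %*% M)
  }
  expect_equal(as.numeric(trace[trace$cycle == 10,
                                c("recurrence_free", "distant_recurrence",
                                  "dead_bc", "dead_other")]),
               occ, tolerance = 1e-10)
})

test_that("degenerate cohorts behave exactly", {
  inp <- no_mortality_inputs()
  # zero recurrence, zero mortality: everyone stays recurrence-free
  sg0 <- subgroup_spec("int", FALSE, 0, Inf, 49.8)
  tr0 <- run_subgroup_cohort(sg0, 0, inp)
  expect_true(all(tr0$recurrence_free == 1))
  expect_true(nrow(tr0) > 50)

  # certain immediate death: everyone in dead_other by cycle 1
  inp1 <- base_inputs()
  inp1$life_table <- synthetic_life_table("flat", q = 1, max_age = 120)
  tr1 <- run_subgroup_cohort(subgroup_spec("x", FALSE, 1e-9, Inf, 49.8),
                             0, inp1)
  expect_equal(tr1$dead_other[tr1$cycle == 1], 1, tolerance = 1e-8)
  expect_equal(nrow(tr1), 2)

  # zero baseline risk (intermediate group, Japanese estimates): no
  # recurrence occupancy regardless of RRR
  tr2 <- subgroup_trace_for_test(base_inputs(), "intermediate", TRUE)
  expect_true(all(tr2$distant_recurrence == 0))
})

test_that("occupancy is conserved across the sensitivity space", {
  inp <- base_inputs()
  set.seed(7)
  for (i in 1:15) {
    risk <- runif(1, 0, 0.378)
    rrr <- runif(1, 0, 0.87)
    mort <- runif(1, 0.2, 0.6)
    treated <- runif(1) < 0.5
    inp_i <- inp
    inp_i$settings$post_recurrence_mortality <- mort
    p <- annual_prob_from_cumulative(chemo_adjusted_risk(risk, rrr, treated),
                                     10)
    horizon <- sample(c(Inf, 10), 1)
    tr <- run_subgroup_cohort(
      subgroup_spec("x", treated, p, horizon, runif(1, 35, 75)),
      as.numeric(treated), inp_i)
    occ <- as.matrix(tr[, c("recurrence_free", "distant_recurrence",
                            "dead_bc", "dead_other")])
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(occ >= 0 & occ <= 1))
    expect_true(all(diff(occ[, "dead_bc"]) >= -1e-15))
    expect_true(all(diff(occ[, "dead_other"]) >= -1e-15))
  }
})

test_that("hazard-bridge inverse holds on the trace at cycle 10", {
  # 10-year recurrence horizon, no competing mortality: cumulative
  # recurrence at cycle 10 equals the 10-year risk
  inp <- no_mortality_inputs()
  inp$settings$post_recurrence_mortality <- 0
  for (risk in c(0.033, 0.248, 0.378)) {
    p <- annual_prob_from_cumulative(risk, 10)
    tr <- run_subgroup_cohort(subgroup_spec("x", FALSE, p, 10, 49.8), 0, inp)
    expect_equal(tr$distant_recurrence[tr$cycle == 10], risk,
                 tolerance = 1e-9)
  }
})

test_that("trace export round-trips through CSV", {
  tr <- run_subgroup_cohort(subgroup_spec("low", FALSE, 0.003, Inf, 49.8),
                            0, base_inputs())
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back), c("cycle", "age", "recurrence_free",
                              "distant_recurrence", "dead_bc", "dead_other"))
  expect_equal(back$recurrence_free, tr$recurrence_free, tolerance = 1e-12)
})
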