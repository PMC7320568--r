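test_that("transition matrix implements the competing-risk split", {
  dz <- disease_params()
  # zero background mortality: disease transitions appear unmodified
  m <- transition_matrix(1, 47, dz, zero_lt())
  expect_equal(unname(m[1, ]), c(0.9, 0.1, 0))
  expect_equal(unname(m[2, ]), c(0, 0.7, 0.3))
  expect_equal(unname(m[3, ]), c(0, 0, 1))
  # with q = 0.01 background death takes precedence in the split
  lt <- life_table(40:60, rep(0.01, 21))
  m <- transition_matrix(1, 47, dz, lt)
  expect_equal(unname(m[1, ]), c(0.891, 0.099, 0.01))
  expect_equal(m[2, 3], 1 - 0.7 * 0.99)
  # relapse is exactly zero outside the schedule
  for (t in c(11, 20, 30))
    expect_identical(transition_matrix(t, 47 + t, dz, lt)[1, 2], 0)
  expect_error(transition_matrix(1, 20, dz, lt), "range error")
})

test_that("rows are stochastic across randomized parameters", {
  set.seed(11)
  lt <- synth_lt()
  for (i in 1:50) {
    dz <- disease_params(
      schedule = relapse_schedule(1, sample(2:10, 1), runif(1)),
      p_cancer_death = runif(1))
    m <- transition_matrix(sample(1:30, 1), runif(1, 0, 115), dz, lt)
    expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-14)
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("cohort occupancy is conserved and death is monotone", {
  set.seed(21)
  for (i in 1:20) {
    spec <- synth_spec(start_age = sample(0:70, 1),
                       discount = runif(1, 0, 0.1))
    strat <- strategy_params("S", runif(1), 30000, 5000)
    res <- run_cohort(strat, spec)
    tr <- res$trace
    occ_sum <- tr$p_no_cancer + tr$p_with_cancer + tr$p_dead
    expect_true(all(abs(occ_sum - 1) < 1e-12))
    expect_true(all(diff(tr$p_dead) >= 0))
    expect_true(all(tr$cost_cycle >= 0 & tr$qaly_cycle >= 0))
    expect_equal(res$os_curve, 1 - tr$p_dead)
    expect_equal(res$os_curve[1], 1)
  }
})

test_that("a cured immortal cohort reproduces the accrual conventions", {
  spec <- immortal_spec(horizon = 30, discount = 0)
  res <- run_cohort(spec$strategy_a, spec)
  expect_equal(res$os_curve, rep(1, 31))
  expect_equal(res$total_qaly, 0.47 + 29 * 0.94)
  expect_equal(res$total_cost, 50000 + 5000 + 30 * 1000)
})

test_that("discounted QALYs of an immortal single-state cohort match the geometric closed form", {
  u <- 0.8
  rho <- 0.05
  n <- 25
  spec <- immortal_spec(horizon = n, discount = rho, u = u)
  res <- run_cohort(spec$strategy_a, spec)
  expect_equal(res$total_qaly, u * sum((1 + rho)^-(1:n)), tolerance = 1e-12)
})

test_that("expected survival of a with-cancer cohort equals (1-d)/d", {
  # q = 0, no relapse, d = 0.3, unit utilities, long horizon: the
  # discounted-QALY total is the expected number of survived years,
  # sum_t (1-d)^t = (1-d)/d
  dz <- disease_params(schedule = relapse_schedule(integer(0), integer(0),
                                                   numeric(0)),
                       p_cancer_death = 0.3,
                       u_no_cancer = 1, u_with_cancer = 1, u_first_year = 1,
                       c_followup = 0, c_palliative = 0)
  spec <- model_spec(strategy_params("A", 0, 0, 0),
                     strategy_params("B", 0, 0, 0), dz,
                     run_settings(start_age = 0, horizon = 200,
                                  discount_rate = 0),
                     zero_lt(250))
  res <- run_cohort(spec$strategy_a, spec)
  expect_equal(res$total_qaly, 0.7 / 0.3, tolerance = 1e-6)
})

test_that("totals are monotone in discount rate and eradication probability", {
  qaly_at <- function(rho, p) {
    spec <- synth_spec(discount = rho)
    run_cohort(strategy_params("S", p, 50000, 5000), spec)
  }
  rhos <- c(0, 0.03, 0.08, 0.2)
  runs <- lapply(rhos, qaly_at, p = 0.9)
  expect_true(all(diff(sapply(runs, `[[`, "total_qaly")) < 0))
  expect_true(all(diff(sapply(runs, `[[`, "total_cost")) < 0))
  ps <- seq(0, 1, by = 0.25)
  qalys <- sapply(ps, function(p) qaly_at(0.03, p)$total_qaly)
  expect_true(all(diff(qalys) > 0))
})

test_that("overall_survival indexes the curve and rejects out-of-range years", {
  spec <- synth_spec()
  res <- run_cohort(spec$strategy_b, spec)
  expect_equal(overall_survival(res, 0), 1)
  expect_equal(overall_survival(res, 5), res$os_curve[6])
  expect_error(overall_survival(res, 31), "range error")
  expect_error(overall_survival(res, -1), "range error")
  # dominance of the higher-eradication arm
  res_a <- run_cohort(spec$strategy_a, spec)
  expect_true(all(res_a$os_curve >= res$os_curve))
})

test_that("expected_outcomes sums the discounted accruals", {
  spec <- synth_spec()
  res <- run_cohort(spec$strategy_a, spec)
  out <- expected_outcomes(res$trace)
  expect_equal(unname(out["cost"]), res$total_cost)
  expect_equal(unname(out["qaly"]), res$total_qaly)
  # a cycle-0-only trace carries the one-time costs and no QALYs
  out0 <- expected_outcomes(res$trace[1, ])
  expect_equal(unname(out0["cost"]), 55000)
  expect_equal(unname(out0["qaly"]), 0)
  # with rho = 0 the discounted totals equal the undiscounted sums
  res0 <- run_cohort(spec$strategy_a, synth_spec(discount = 0))
  expect_equal(res0$total_cost, sum(res0$trace$cost_cycle))
  expect_equal(res0$total_qaly, sum(res0$trace$qaly_cycle))
})

test_that("zero background mortality makes the run age-independent", {
  dz <- disease_params()
  for (age in c(0, 25, 47, 70)) {
    spec <- model_spec(strategy_params("A", 0.9, 50000, 5000),
                       strategy_params("B", 0.73, 12000, 5000), dz,
                       run_settings(start_age = age, horizon = 30,
                                    discount_rate = 0.03), zero_lt())
    res <- run_cohort(spec$strategy_a, spec)
    if (age == 0) ref <- res
    expect_equal(res$total_qaly, ref$total_qaly, tolerance = 1e-14)
    expect_equal(res$total_cost, ref$total_cost, tolerance = 1e-14)
  }
})

test_that("trace CSV uses the documented column headers", {
  spec <- synth_spec()
  res <- run_cohort(spec$strategy_a, spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(res, path)
  expect_identical(readLines(path, n = 1),
                   paste("cycle,age,p_no_cancer,p_with_cancer,p_dead",
                         "cost_cycle,qaly_cycle,disc_cost_cum,disc_qaly_cum",
                         sep = ","))
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 31)
  expect_equal(back$p_dead, res$trace$p_dead)
})

test_that("the vectorised totals engine agrees with the reference trace", {
  engine_totals <- function(spec, strat) {
    pbtcea:::cohort_totals_vec(
      spec, strat$p_eradicate, strat$c_radiotherapy, strat$c_chemo,
      spec$disease$p_cancer_death, spec$disease$u_no_cancer,
      spec$disease$u_with_cancer, spec$disease$u_first_year,
      spec$disease$c_followup, spec$disease$c_palliative)
  }
  for (spec in list(synth_spec(), synth_spec(start_age = 60),
                    immortal_spec(discount = 0.03))) {
    for (strat in list(spec$strategy_a, spec$strategy_b)) {
      ref <- run_cohort(strat, spec)
      vec <- engine_totals(spec, strat)
      expect_equal(vec$cost, ref$total_cost, tolerance = 1e-12)
      expect_equal(vec$qaly, ref$total_qaly, tolerance = 1e-12)
    }
  }
})

test_that("degenerate horizons are forced to one cycle with a warning", {
  expect_warning(s <- run_settings(start_age = 80), "forcing horizon")
  expect_equal(s$horizon, 1L)
  expect_error(run_settings(horizon = 0), "horizon")
})
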