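test_that("fit_distribution moment-matches beta and truncates normal at 0", {
  set.seed(41)
  # symmetric interval: empirical quantiles reproduce the stated CI
  sym <- fit_distribution(param_dist("u_no_cancer", "beta", 0.5,
                                     c(0.4, 0.6)))(2e5)
  qq <- quantile(sym, c(0.05, 0.5, 0.95))
  expect_equal(unname(qq[1]), 0.4, tolerance = 0.01)
  expect_equal(unname(qq[3]), 0.6, tolerance = 0.01)
  expect_equal(unname(qq[2]), 0.5, tolerance = 0.005)  # symmetry
  # published eradication-probability interval
  erad <- fit_distribution(param_dist("p_eradicate_a", "beta", 0.9,
                                      c(0.833, 0.957)))(2e5)
  expect_equal(unname(quantile(erad, 0.05)), 0.833, tolerance = 0.01)
  expect_equal(unname(quantile(erad, 0.95)), 0.957, tolerance = 0.01)
  # normal sampler: correct centre, never negative
  cost <- fit_distribution(param_dist("c_followup", "normal", 50,
                                      c(-200, 300)))(2e4)
  expect_true(all(cost >= 0))
  # degenerate interval is a point mass
  pm <- fit_distribution(param_dist("c_chemo", "normal", 5000,
                                    c(5000, 5000)))(100)
  expect_identical(pm, rep(5000, 100))
  # infeasible beta moments are refused
  expect_error(fit_distribution(param_dist("p_cancer_death", "beta", 0.02,
                                           c(0.001, 0.5)))(1),
               "infeasible-moments")
})

test_that("param_dist validates its interval and family", {
  expect_error(param_dist("u_no_cancer", "beta", 0.5, c(0.6, 0.7)),
               "invalid-spec")
  expect_error(param_dist("u_no_cancer", "beta", 1.2, c(0.9, 1.3)),
               "invalid-spec")
  expect_error(param_dist("nonexistent", "beta", 0.5, c(0.4, 0.6)))
})

test_that("set_param reaches every supported path and ties tied utilities", {
  spec <- synth_spec()
  expect_equal(set_param(spec, "p_eradicate_a", 0.8)$strategy_a$p_eradicate,
               0.8)
  expect_equal(set_param(spec, "c_radiotherapy_b", 1)$strategy_b$c_radiotherapy,
               1)
  s2 <- set_param(spec, "c_chemo", 123)
  expect_equal(s2$strategy_a$c_chemo, 123)
  expect_equal(s2$strategy_b$c_chemo, 123)
  s3 <- set_param(spec, "u_with_cancer", 0.6)
  expect_equal(s3$disease$u_with_cancer, 0.6)
  expect_equal(s3$disease$u_first_year, 0.6)
  expect_equal(set_param(spec, "p_cancer_death", 0.5)$disease$p_cancer_death,
               0.5)
})

test_that("PSA is seed-reproducible and recovers its input distributions", {
  spec <- synth_spec()
  p1 <- run_psa(spec, n = 2000, seed = 7)
  p2 <- run_psa(spec, n = 2000, seed = 7)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$fraction_favoring_a, p2$fraction_favoring_a)
  expect_equal(nrow(p1$draws), 2000)
  expect_true(p1$fraction_favoring_a >= 0 && p1$fraction_favoring_a <= 1)
  # sample mean of each parameter within 3 SE of its distribution mean
  for (d in base_case_distributions()) {
    x <- p1$param_draws[[d$param]]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - d$mean), 3 * se + 1e-12)
  }
  # NMB recorded per draw is consistent with the deltas
  expect_equal(p1$draws$nmb,
               p1$wtp * p1$draws$delta_qaly - p1$draws$delta_cost)
})

test_that("degenerate distributions reduce the PSA to the base case", {
  spec <- synth_spec()
  point <- lapply(base_case_distributions(), function(d)
    param_dist(d$param, d$kind, d$mean, c(d$mean, d$mean)))
  psa <- run_psa(spec, point, n = 50, seed = 1)
  fit <- cea(spec)
  expect_equal(unique(psa$draws$delta_cost), fit$comparison$delta_cost,
               tolerance = 1e-10)
  expect_equal(unique(psa$draws$delta_qaly), fit$comparison$delta_effect,
               tolerance = 1e-10)
  # the base case is cost-effective, so every iteration favors a
  expect_equal(psa$fraction_favoring_a, 1)
})

test_that("two seeds give fractions within Monte Carlo noise of each other", {
  spec <- synth_spec()
  n <- 4000
  f1 <- run_psa(spec, n = n, seed = 1)$fraction_favoring_a
  f2 <- run_psa(spec, n = n, seed = 2)$fraction_favoring_a
  p <- (f1 + f2) / 2
  se <- sqrt(2 * p * (1 - p) / n)
  expect_lt(abs(f1 - f2), 3 * se)
})

test_that("tornado ranks parameters by ICER spread", {
  spec <- synth_spec()
  dists <- base_case_distributions()
  tor <- tornado(spec, dists)
  expect_setequal(tor$param, vapply(dists, `[[`, "", "param"))
  expect_true(all(diff(tor$spread) <= 0))
  expect_true(all(tor$spread >= 0))
  expect_setequal(tor$param[1:3],
                  c("p_eradicate_a", "p_eradicate_b", "c_radiotherapy_a"))
  expect_lt(tor$spread[tor$param == "c_followup"],
            tor$spread[tor$param == "c_radiotherapy_a"])
  # a degenerate interval has zero spread and ranks last
  dists[[5]] <- param_dist("c_chemo", "normal", 5000, c(5000, 5000))
  tor2 <- tornado(spec, dists)
  expect_equal(tor2$param[nrow(tor2)], "c_chemo")
  expect_equal(tor2$spread[nrow(tor2)], 0, tolerance = 1e-9)
})

test_that("one-way thresholds are self-consistent fixed points", {
  spec <- synth_spec()
  base_icer <- cea(spec)$comparison$icer
  # with wtp set to the base-case ICER the threshold is the base value
  thr <- one_way_threshold(spec, "c_radiotherapy_a", wtp = base_icer,
                           lower = 12000, upper = 200000)
  expect_equal(thr$threshold, 50000, tolerance = 1e-4)
  # re-evaluating the model at any returned threshold reproduces wtp
  for (par in c("c_radiotherapy_a", "p_eradicate_a", "p_eradicate_b")) {
    t2 <- one_way_threshold(spec, par, wtp = 30828)
    expect_lt(abs(t2$icer_check - 30828) / 30828, 1e-4)
  }
  expect_equal(one_way_threshold(spec, "c_radiotherapy_a", 30828)$direction,
               "maximum")
  expect_equal(one_way_threshold(spec, "p_eradicate_a", 30828,
                                 lower = 0.75, upper = 0.999)$direction,
               "minimum")
  expect_error(one_way_threshold(spec, "c_followup", wtp = 30828,
                                 lower = 900, upper = 1100),
               "no-threshold-in-range")
})

test_that("age stratification runs to the endpoint and is monotone", {
  spec <- synth_spec()
  strat <- age_stratified_icer(spec, ages = seq(0, 70, by = 10))
  expect_equal(strat$age, seq(0, 70, by = 10))
  expect_true(all(diff(strat$icer) > 0))
  expect_true(all(strat$delta_qaly > 0))
  expect_error(age_stratified_icer(spec, ages = c(40, 80)), "invalid-age")
  thr <- age_threshold(spec, wtp = 30828)
  expect_true(thr %in% 0:76)
  # the returned age is the crossing point of the monotone ICER curve
  all_ages <- age_stratified_icer(spec, 0:76)
  expect_true(all_ages$icer[all_ages$age == thr] <= 30828)
  expect_true(all_ages$icer[all_ages$age == thr + 1] > 30828)
  expect_error(age_threshold(spec, wtp = 1), "no-crossing")
  expect_error(age_threshold(spec, wtp = 1e9), "no-crossing")
})
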