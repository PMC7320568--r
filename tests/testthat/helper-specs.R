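# Shared fixtures, all built in code: a zero-mortality table for analytic
# checks, the synthetic Gompertz-Makeham table for self-contained runs,
# and small model specifications around them.

zero_lt <- function(max_age = 130) {
  life_table(0:max_age, rep(0, max_age + 1), provenance = "zero")
}

synth_lt <- function() synth_life_table()

# base-case parameterization on a synthetic life table (no fixture needed)
synth_spec <- function(start_age = 47, horizon = NULL, discount = 0.03) {
  model_spec(
    strategy_params("IMPT", 0.9, 50000, 5000),
    strategy_params("IMRT", 0.73, 12000, 5000),
    disease_params(),
    run_settings(start_age = start_age, horizon = horizon,
                 discount_rate = discount),
    synth_lt())
}

# degenerate spec: certain eradication, no relapse, no background death
immortal_spec <- function(horizon = 30, discount = 0, u = NULL) {
  dz <- if (is.null(u)) {
    disease_params(schedule = relapse_schedule(integer(0), integer(0),
                                               numeric(0)))
  } else {
    disease_params(schedule = relapse_schedule(integer(0), integer(0),
                                               numeric(0)),
                   u_no_cancer = u, u_with_cancer = u, u_first_year = u)
  }
  model_spec(
    strategy_params("A", 1, 50000, 5000),
    strategy_params("B", 1, 12000, 5000),
    dz,
    run_settings(start_age = 47, horizon = horizon,
                 discount_rate = discount),
    zero_lt())
}

fake_result <- function(cost, qaly, name = "X") {
  structure(list(strategy = name, total_cost = cost, total_qaly = qaly,
                 os_curve = 1,
                 settings = run_settings(horizon = 1)),
            class = "run_result")
}

base_config_path <- function() {
  system.file("extdata", "base_case.yaml", package = "pbtcea")
}
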