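#' Patient-level Monte Carlo simulation of one strategy
#'
#' Simulates `n` individual trajectories under exactly the transition
#' rules and reward conventions of the deterministic cohort engine
#' ([run_cohort()]), so the sample means are an unbiased brute-force
#' estimate of the cohort totals. Draw order from a single RNG stream:
#' first `n` uniforms decide the initial state (eradicated vs not), then
#' one uniform per patient per cycle drives the yearly transition via the
#' inverse CDF with category order (death, relapse, stay) from
#' `no_cancer` and (death, stay) from `with_cancer`. Dead patients keep
#' consuming a draw per cycle so that the stream layout is independent of
#' outcomes.
#'
#' @param strategy a [strategy_params()].
#' @param spec a [model_spec()].
#' @param n number of patients (>= 1).
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @param keep_trajectories if `TRUE`, retain the per-patient, per-year
#'   state matrix (memory ~ `n * horizon`; intended for small `n`).
#' @return an object of class `"microsim_estimate"`: list with `n`,
#'   `seed`, `mean_cost`, `se_cost`, `mean_qaly`, `se_qaly`, `os_curve`
#'   (empirical OS(0..horizon)) and, optionally, `states` (an
#'   `n x (horizon+1)` integer matrix, 1 = no cancer, 2 = with cancer,
#'   3 = dead) plus per-patient `cost` and `qaly`.
#' @export
#' @examples
#' spec <- base_case_spec(synth_life_table())
#' simulate_patients(spec$strategy_b, spec, n = 2000, seed = 42)
simulate_patients <- function(strategy, spec, n, seed = NULL,
                              keep_trajectories = FALSE) {
  stopifnot(inherits(strategy, "strategy_params"),
            inherits(spec, "model_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  nh <- spec$settings$horizon
  dz <- spec$disease
  ci <- cycle_inputs(spec)
  state <- ifelse(stats::runif(n) < strategy$p_eradicate, 1L, 2L)
  cost <- rep(strategy$c_radiotherapy + strategy$c_chemo, n)
  qaly <- numeric(n)
  alive_frac <- numeric(nh + 1)
  alive_frac[1] <- 1
  states <- NULL
  if (keep_trajectories) {
    states <- matrix(NA_integer_, n, nh + 1)
    states[, 1] <- state
  }
  d <- dz$p_cancer_death
  for (t in seq_len(nh)) {
    u <- stats::runif(n)
    q <- ci$q[t]; r <- ci$r[t]
    new <- state
    nc <- state == 1L
    wc <- state == 2L
    # no_cancer: death if u < q; relapse if u < q + r(1-q); else stay
    new[nc & u < q] <- 3L
    new[nc & u >= q & u < q + r * (1 - q)] <- 2L
    # with_cancer: death if u < 1 - (1-d)(1-q); else stay
    new[wc & u < 1 - (1 - d) * (1 - q)] <- 3L
    state <- new
    u_nc <- if (t == 1) dz$u_first_year else dz$u_no_cancer
    u_wc <- if (t == 1) dz$u_first_year else dz$u_with_cancer
    cost <- cost + ci$disc[t] *
      ((state == 1L) * dz$c_followup +
       (state == 2L) * (dz$c_followup + dz$c_palliative))
    qaly <- qaly + ci$disc[t] *
      ((state == 1L) * u_nc + (state == 2L) * u_wc)
    alive_frac[t + 1] <- mean(state != 3L)
    if (keep_trajectories) states[, t + 1] <- state
  }
  out <- list(n = n, seed = seed,
              mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
              mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n),
              os_curve = alive_frac, strategy = strategy$name)
  if (keep_trajectories) {
    out$states <- states
    out$cost <- cost
    out$qaly <- qaly
  }
  structure(out, class = "microsim_estimate")
}

#' @export
print.microsim_estimate <- function(x, ...) {
  cat(sprintf("Microsimulation [%s]: n = %d%s\n", x$strategy, x$n,
              if (is.null(x$seed)) "" else sprintf(" (seed %d)", x$seed)))
  cat(sprintf("  mean cost $%.1f (SE %.1f), mean QALY %.3f (SE %.4f)\n",
              x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  invisible(x)
}

#' Export simulated trajectories as a long-format table
#'
#' One row per patient-year with columns `patient_id`, `year`, `age`,
#' `state` (`NO_CANCER` / `WITH_CANCER` / `DEAD`), `cost_accrued`,
#' `qaly_accrued` (discounted accruals of that year; year 0 carries the
#' one-time treatment cost). Rows stop after the year a patient dies.
#'
#' @param est a [simulate_patients()] result with
#'   `keep_trajectories = TRUE`.
#' @param spec the [model_spec()] used for the simulation.
#' @param strategy the [strategy_params()] used for the simulation.
#' @param path optional destination; when given, the table is written as
#'   CSV.
#' @return the trajectory data frame (invisibly when `path` is given).
#' @export
export_trajectories <- function(est, spec, strategy, path = NULL) {
  stopifnot(inherits(est, "microsim_estimate"), !is.null(est$states))
  nh <- spec$settings$horizon
  dz <- spec$disease
  ci <- cycle_inputs(spec)
  labels <- c("NO_CANCER", "WITH_CANCER", "DEAD")
  rows <- vector("list", est$n)
  for (i in seq_len(est$n)) {
    st <- est$states[i, ]
    died <- match(3L, st)
    last <- if (is.na(died)) nh + 1L else died
    yr <- 0:(last - 1L)
    cost <- numeric(last)
    qa <- numeric(last)
    cost[1] <- strategy$c_radiotherapy + strategy$c_chemo
    for (t in seq_len(last - 1L)) {
      s_t <- st[t + 1L]
      u_nc <- if (t == 1) dz$u_first_year else dz$u_no_cancer
      u_wc <- if (t == 1) dz$u_first_year else dz$u_with_cancer
      cost[t + 1L] <- ci$disc[t] *
        ((s_t == 1L) * dz$c_followup +
         (s_t == 2L) * (dz$c_followup + dz$c_palliative))
      qa[t + 1L] <- ci$disc[t] * ((s_t == 1L) * u_nc + (s_t == 2L) * u_wc)
    }
    rows[[i]] <- data.frame(patient_id = i, year = yr,
                            age = spec$settings$start_age + yr,
                            state = labels[st[seq_len(last)]],
                            cost_accrued = cost, qaly_accrued = qa)
  }
  out <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Paired Monte Carlo strategy selection
#'
#' First-order (patient-level) Monte Carlo comparison of the two
#' strategies: each trial simulates one patient under each arm using
#' common random numbers — the same uniform decides tumour eradication in
#' both arms, and the same per-year uniform drives both transitions — so
#' the two trajectories diverge only where the strategies genuinely
#' differ (chiefly when the eradication draw falls between the two
#' eradication probabilities). Per trial the incremental cost,
#' incremental effectiveness and net monetary benefit
#' `wtp * dE - dC` are recorded; a trial favors strategy a when its NMB
#' is positive (ties count as not favoring). This is the machinery behind
#' a trials-distribution scatter and strategy-selection chart, and is
#' distinct from the parameter-uncertainty PSA of [run_psa()].
#'
#' @param spec a [model_spec()].
#' @param n number of trials.
#' @param seed integer RNG seed.
#' @param wtp willingness-to-pay in US$/QALY.
#' @return an object of class `"mc_selection"`: list with `draws`
#'   (data frame: trial, delta_cost, delta_qaly, nmb),
#'   `fraction_favoring_a`, `n`, `seed`, `wtp`.
#' @export
mc_strategy_selection <- function(spec, n = 50000, seed = 1, wtp = 30828) {
  stopifnot(inherits(spec, "model_spec"), n >= 1)
  set.seed(seed)
  nh <- spec$settings$horizon
  dz <- spec$disease
  ci <- cycle_inputs(spec)
  d <- dz$p_cancer_death
  u0 <- stats::runif(n)
  state_a <- ifelse(u0 < spec$strategy_a$p_eradicate, 1L, 2L)
  state_b <- ifelse(u0 < spec$strategy_b$p_eradicate, 1L, 2L)
  cost_a <- rep(spec$strategy_a$c_radiotherapy + spec$strategy_a$c_chemo, n)
  cost_b <- rep(spec$strategy_b$c_radiotherapy + spec$strategy_b$c_chemo, n)
  qaly_a <- qaly_b <- numeric(n)
  step <- function(state, u, q, r) {
    new <- state
    nc <- state == 1L
    wc <- state == 2L
    new[nc & u < q] <- 3L
    new[nc & u >= q & u < q + r * (1 - q)] <- 2L
    new[wc & u < 1 - (1 - d) * (1 - q)] <- 3L
    new
  }
  for (t in seq_len(nh)) {
    u <- stats::runif(n)
    q <- ci$q[t]; r <- ci$r[t]
    state_a <- step(state_a, u, q, r)
    state_b <- step(state_b, u, q, r)
    u_nc <- if (t == 1) dz$u_first_year else dz$u_no_cancer
    u_wc <- if (t == 1) dz$u_first_year else dz$u_with_cancer
    cost_a <- cost_a + ci$disc[t] *
      ((state_a == 1L) * dz$c_followup +
       (state_a == 2L) * (dz$c_followup + dz$c_palliative))
    cost_b <- cost_b + ci$disc[t] *
      ((state_b == 1L) * dz$c_followup +
       (state_b == 2L) * (dz$c_followup + dz$c_palliative))
    qaly_a <- qaly_a + ci$disc[t] * ((state_a == 1L) * u_nc +
                                     (state_a == 2L) * u_wc)
    qaly_b <- qaly_b + ci$disc[t] * ((state_b == 1L) * u_nc +
                                     (state_b == 2L) * u_wc)
  }
  dc <- cost_a - cost_b
  de <- qaly_a - qaly_b
  nmb <- wtp * de - dc
  structure(list(draws = data.frame(trial = seq_len(n), delta_cost = dc,
                                    delta_qaly = de, nmb = nmb),
                 fraction_favoring_a = mean(nmb > 0),
                 n = n, seed = seed, wtp = wtp),
            class = "mc_selection")
}

#' @export
print.mc_selection <- function(x, ...) {
  cat(sprintf(
    "Paired Monte Carlo strategy selection: %d trials (seed %d)\n",
    x$n, x$seed))
  cat(sprintf("  at WTP $%s/QALY, %.1f%% of trials favor strategy a\n",
              format(x$wtp, big.mark = ","),
              100 * x$fraction_favoring_a))
  invisible(x)
}

#' Summary JSON for a microsimulation estimate
#'
#' @param est a [simulate_patients()] result.
#' @param path destination path for the JSON summary.
#' @return `path`, invisibly.
#' @export
write_microsim_summary <- function(est, path) {
  stopifnot(inherits(est, "microsim_estimate"))
  jsonlite::write_json(
    list(n = est$n, seed = est$seed, mean_cost = est$mean_cost,
         se_cost = est$se_cost, mean_qaly = est$mean_qaly,
         se_qaly = est$se_qaly, os_curve = est$os_curve),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
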