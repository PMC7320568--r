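#' Per-cycle transition matrix of the 3-state model
#'
#' States are `no_cancer`, `with_cancer`, `dead`. Background mortality
#' (from the life table, at the age attained during the cycle) competes
#' multiplicatively with the disease transitions, background death taking
#' precedence in the split:
#' \itemize{
#'   \item from `no_cancer`: death `q`, relapse `r(t) * (1 - q)`,
#'     stay `(1 - r(t)) * (1 - q)`;
#'   \item from `with_cancer`: death `1 - (1 - d) * (1 - q)`, stay the
#'     complement, where `d` is the annual cancer-death probability;
#'   \item `dead` is absorbing.
#' }
#'
#' @param cycle_index cycle number t >= 1; indexes the relapse schedule.
#' @param current_age age in years attained during the cycle; looked up in
#'   the life table (clamped above its maximum, certain death from 120).
#' @param disease a [disease_params()].
#' @param life_table a [life_table()].
#' @return a 3x3 row-stochastic matrix with dimnames
#'   `c("no_cancer", "with_cancer", "dead")`.
#' @export
#' @examples
#' transition_matrix(1, 47, disease_params(), synth_life_table())
transition_matrix <- function(cycle_index, current_age, disease, life_table) {
  stopifnot(cycle_index >= 1, inherits(disease, "disease_params"))
  q <- q_lookup(life_table, current_age)
  r <- relapse_prob(disease$schedule, cycle_index)
  d <- disease$p_cancer_death
  m <- matrix(c((1 - r) * (1 - q), r * (1 - q),       q,
                0,                 (1 - d) * (1 - q), 1 - (1 - d) * (1 - q),
                0,                 0,                 1),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("no_cancer", "with_cancer", "dead"),
                              c("no_cancer", "with_cancer", "dead")))
  m
}

# Per-cycle vectors of background mortality and relapse probability for a
# run: q[t] uses the age attained during cycle t, start_age + t - 1.
cycle_inputs <- function(spec) {
  n <- spec$settings$horizon
  t <- seq_len(n)
  list(q = q_lookup(spec$life_table, spec$settings$start_age + t - 1),
       r = relapse_prob(spec$disease$schedule, t),
       disc = (1 + spec$settings$discount_rate)^(-t))
}

#' Run the deterministic Markov cohort trace for one strategy
#'
#' Cycle 0 places the cohort at `(p_eradicate, 1 - p_eradicate, 0)` over
#' (`no_cancer`, `with_cancer`, `dead`) and charges the one-time
#' radiotherapy + chemotherapy cost, undiscounted. Each cycle `t >= 1`
#' applies the cycle's transition matrix and then accrues state rewards at
#' cycle end, discounted by `(1 + rho)^(-t)`: follow-up cost for every
#' alive state, palliative cost additionally for `with_cancer`; utility
#' `u_first_year` for both alive states at `t = 1`, state-specific
#' utilities from `t = 2`. Death accrues nothing. No half-cycle correction
#' is applied.
#'
#' @param strategy a [strategy_params()].
#' @param spec a [model_spec()] (its `strategy_a`/`strategy_b` slots are
#'   ignored; the `strategy` argument decides the arm).
#' @return an object of class `"run_result"`: list with `total_cost`,
#'   `total_qaly` (discounted), `os_curve` (OS(0..horizon)), `trace` (a
#'   data frame, one row per cycle) and `strategy`.
#' @export
#' @examples
#' spec <- base_case_spec(synth_life_table())
#' res <- run_cohort(spec$strategy_b, spec)
#' overall_survival(res, 5)
run_cohort <- function(strategy, spec) {
  stopifnot(inherits(strategy, "strategy_params"),
            inherits(spec, "model_spec"))
  n <- spec$settings$horizon
  dz <- spec$disease
  ci <- cycle_inputs(spec)
  occ <- matrix(0, nrow = n + 1, ncol = 3,
                dimnames = list(NULL, c("no_cancer", "with_cancer", "dead")))
  occ[1, ] <- c(strategy$p_eradicate, 1 - strategy$p_eradicate, 0)
  cost <- qaly <- numeric(n + 1)
  cost[1] <- strategy$c_radiotherapy + strategy$c_chemo
  disc_cost <- disc_qaly <- numeric(n + 1)
  disc_cost[1] <- cost[1]
  for (t in seq_len(n)) {
    m <- transition_matrix(t, spec$settings$start_age + t - 1, dz,
                           spec$life_table)
    occ[t + 1, ] <- occ[t, ] %*% m
    u_nc <- if (t == 1) dz$u_first_year else dz$u_no_cancer
    u_wc <- if (t == 1) dz$u_first_year else dz$u_with_cancer
    cost[t + 1] <- occ[t + 1, 1] * dz$c_followup +
      occ[t + 1, 2] * (dz$c_followup + dz$c_palliative)
    qaly[t + 1] <- occ[t + 1, 1] * u_nc + occ[t + 1, 2] * u_wc
    disc_cost[t + 1] <- cost[t + 1] * ci$disc[t]
    disc_qaly[t + 1] <- qaly[t + 1] * ci$disc[t]
  }
  trace <- data.frame(
    cycle = 0:n,
    age = spec$settings$start_age + c(0, seq_len(n) - 1),
    p_no_cancer = occ[, 1], p_with_cancer = occ[, 2], p_dead = occ[, 3],
    cost_cycle = cost, qaly_cycle = qaly,
    disc_cost_cum = cumsum(disc_cost), disc_qaly_cum = cumsum(disc_qaly))
  structure(list(strategy = strategy$name,
                 total_cost = sum(disc_cost), total_qaly = sum(disc_qaly),
                 os_curve = 1 - occ[, 3], trace = trace,
                 settings = spec$settings),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("Cohort run [%s]: %d cycles from age %g\n", x$strategy,
              x$settings$horizon, x$settings$start_age))
  cat(sprintf("  discounted cost $%.1f, %.2f QALYs; OS(end) = %.3f\n",
              x$total_cost, x$total_qaly,
              x$os_curve[length(x$os_curve)]))
  invisible(x)
}

#' Overall survival at a given year
#'
#' OS(t) = 1 - Pr(dead by end of cycle t); OS(0) = 1.
#'
#' @param result a [run_cohort()] result.
#' @param year integer in `0:horizon` (vectorised).
#' @return survival probability.
#' @export
overall_survival <- function(result, year) {
  stopifnot(inherits(result, "run_result"))
  if (any(year < 0 | year > result$settings$horizon))
    stop("range error: year outside 0..horizon")
  result$os_curve[year + 1]
}

#' Discounted totals from a cohort trace
#'
#' @param trace the `trace` data frame of a [run_cohort()] result.
#' @return named numeric vector `c(cost = , qaly = )` of discounted totals.
#' @export
expected_outcomes <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("disc_cost_cum", "disc_qaly_cum") %in% names(trace)))
  c(cost = trace$disc_cost_cum[nrow(trace)],
    qaly = trace$disc_qaly_cum[nrow(trace)])
}

#' Write a cohort trace as CSV
#'
#' Columns (bit-exact headers): cycle, age, p_no_cancer, p_with_cancer,
#' p_dead, cost_cycle, qaly_cycle, disc_cost_cum, disc_qaly_cum.
#'
#' @param result a [run_cohort()] result.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  stopifnot(inherits(result, "run_result"))
  utils::write.csv(result$trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Vectorised discounted totals across parameter draws. Every argument
# after `spec` may be a scalar or a vector of length m (one entry per
# draw); q/r come from the spec's life table and schedule, which are not
# sampled. Implements exactly the conventions of run_cohort; used by the
# PSA so that 50,000 reruns stay cheap. Returns list(cost, qaly) length m.
cohort_totals_vec <- function(spec, p_eradicate, c_rt, c_chemo,
                              p_cancer_death, u_no_cancer, u_with_cancer,
                              u_first_year, c_followup, c_palliative) {
  ci <- cycle_inputs(spec)
  n <- spec$settings$horizon
  m <- max(length(p_eradicate), length(c_rt), length(c_chemo),
           length(p_cancer_death), length(u_no_cancer),
           length(u_with_cancer), length(u_first_year),
           length(c_followup), length(c_palliative))
  p_nc <- rep_len(p_eradicate, m)
  p_wc <- 1 - p_nc
  cost <- rep_len(c_rt, m) + rep_len(c_chemo, m)
  qaly <- numeric(m)
  d <- rep_len(p_cancer_death, m)
  for (t in seq_len(n)) {
    q <- ci$q[t]; r <- ci$r[t]
    new_nc <- p_nc * (1 - r) * (1 - q)
    new_wc <- p_nc * r * (1 - q) + p_wc * (1 - d) * (1 - q)
    p_nc <- new_nc; p_wc <- new_wc
    u_nc <- if (t == 1) u_first_year else u_no_cancer
    u_wc <- if (t == 1) u_first_year else u_with_cancer
    cost <- cost + ci$disc[t] *
      (p_nc * c_followup + p_wc * (c_followup + c_palliative))
    qaly <- qaly + ci$disc[t] * (p_nc * u_nc + p_wc * u_wc)
  }
  list(cost = cost, qaly = qaly)
}
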