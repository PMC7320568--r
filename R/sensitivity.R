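#' Sampling specification for one uncertain parameter
#'
#' Parameters are described, as in the source tables of typical
#' cost-effectiveness reports, by a mean and a 90% confidence interval
#' plus a distribution family: `"beta"` for probabilities and utilities,
#' `"normal"` (truncated at 0) for costs. See [fit_distribution()] for how
#' the interval is turned into distribution parameters.
#'
#' @param param parameter path; one of
#'   `p_eradicate_a`, `p_eradicate_b`, `c_radiotherapy_a`,
#'   `c_radiotherapy_b`, `c_chemo`, `c_followup`, `c_palliative`,
#'   `u_no_cancer`, `u_with_cancer`, `p_cancer_death`.
#' @param kind `"beta"` or `"normal"`.
#' @param mean distribution mean (the base-case value).
#' @param ci90 length-2 numeric, the 5th and 95th percentiles. A
#'   degenerate interval (`low == high == mean`) yields a point mass.
#' @return an object of class `"param_dist"`.
#' @export
param_dist <- function(param, kind = c("beta", "normal"), mean, ci90) {
  kind <- match.arg(kind)
  param <- match.arg(param, .param_paths)
  stopifnot(length(ci90) == 2, is.finite(mean), all(is.finite(ci90)))
  if (!(ci90[1] == ci90[2] && ci90[1] == mean) &&
      !(ci90[1] < mean && mean < ci90[2]))
    stop("invalid-spec: need ci90[1] < mean < ci90[2] (or a degenerate interval)")
  if (kind == "beta" && (mean < 0 || mean > 1 || ci90[1] < 0 || ci90[2] > 1))
    stop("invalid-spec: beta distributions require values in [0,1]")
  structure(list(param = param, kind = kind, mean = mean,
                 ci90 = as.numeric(ci90)),
            class = "param_dist")
}

.param_paths <- c("p_eradicate_a", "p_eradicate_b", "c_radiotherapy_a",
                  "c_radiotherapy_b", "c_chemo", "c_followup",
                  "c_palliative", "u_no_cancer", "u_with_cancer",
                  "p_cancer_death")

#' Replace one parameter in a model specification
#'
#' `c_chemo` is charged in both arms, so setting it updates both
#' strategies. `u_with_cancer` also sets the first-year utility, which the
#' model ties to the with-cancer health state (the first year after
#' radiotherapy carries the treatment disutility 0.47 in both alive
#' states).
#'
#' @param spec a [model_spec()].
#' @param param a parameter path (see [param_dist()]).
#' @param value new value.
#' @return the modified [model_spec()].
#' @export
set_param <- function(spec, param, value) {
  stopifnot(inherits(spec, "model_spec"))
  param <- match.arg(param, .param_paths)
  switch(param,
    p_eradicate_a = spec$strategy_a$p_eradicate <- value,
    p_eradicate_b = spec$strategy_b$p_eradicate <- value,
    c_radiotherapy_a = spec$strategy_a$c_radiotherapy <- value,
    c_radiotherapy_b = spec$strategy_b$c_radiotherapy <- value,
    c_chemo = {
      spec$strategy_a$c_chemo <- value
      spec$strategy_b$c_chemo <- value
    },
    c_followup = spec$disease$c_followup <- value,
    c_palliative = spec$disease$c_palliative <- value,
    u_no_cancer = spec$disease$u_no_cancer <- value,
    u_with_cancer = {
      spec$disease$u_with_cancer <- value
      spec$disease$u_first_year <- value
    },
    p_cancer_death = spec$disease$p_cancer_death <- value)
  spec
}

#' The base-case parameter distributions
#'
#' The ten uncertain parameters with their means and 90% intervals: beta
#' for the eradication probabilities, utilities and the cancer-death
#' probability; truncated normal for the five costs.
#'
#' @return a list of [param_dist()] objects.
#' @export
base_case_distributions <- function() {
  list(
    param_dist("p_eradicate_a", "beta", 0.9, c(0.833, 0.957)),
    param_dist("p_eradicate_b", "beta", 0.73, c(0.665, 0.792)),
    param_dist("c_radiotherapy_a", "normal", 50000, c(37258.3, 62775.4)),
    param_dist("c_radiotherapy_b", "normal", 12000, c(10723.2, 13287.5)),
    param_dist("c_chemo", "normal", 5000, c(3710.4, 6284.7)),
    param_dist("c_followup", "normal", 1000, c(872.1, 1127.8)),
    param_dist("c_palliative", "normal", 5000, c(3724.0, 6269.1)),
    param_dist("u_no_cancer", "beta", 0.94, c(0.822, 1)),
    param_dist("u_with_cancer", "beta", 0.47, c(0.343, 0.598)),
    param_dist("p_cancer_death", "beta", 0.3, c(0.237, 0.365)))
}

#' Turn a parameter distribution into a sampler
#'
#' The 90% interval half-width is converted to a standard deviation via
#' the normal quantile, `sd = (high - low) / (2 * 1.645)`. Beta parameters
#' are moment-matched: `alpha = m * (m * (1 - m) / sd^2 - 1)`,
#' `beta = alpha * (1 - m) / m`. Normal samplers redraw until the value is
#' non-negative (truncation at 0). A degenerate interval gives a
#' point-mass sampler. Samplers use R's global RNG stream, so
#' `set.seed()` makes draws reproducible.
#'
#' @param dist a [param_dist()].
#' @return `function(n)` returning `n` draws.
#' @export
#' @examples
#' set.seed(1)
#' s <- fit_distribution(param_dist("p_eradicate_a", "beta", 0.9,
#'                                  c(0.833, 0.957)))
#' quantile(s(10000), c(0.05, 0.95))
fit_distribution <- function(dist) {
  stopifnot(inherits(dist, "param_dist"))
  m <- dist$mean
  if (dist$ci90[1] == dist$ci90[2])
    return(function(n) rep(m, n))
  sd <- (dist$ci90[2] - dist$ci90[1]) / (2 * qnorm(0.95))
  if (dist$kind == "beta") {
    if (sd^2 >= m * (1 - m))
      stop("infeasible-moments: implied variance >= m(1-m) for beta")
    alpha <- m * (m * (1 - m) / sd^2 - 1)
    beta <- alpha * (1 - m) / m
    function(n) stats::rbeta(n, alpha, beta)
  } else {
    function(n) {
      x <- stats::rnorm(n, m, sd)
      while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), m, sd)
      x
    }
  }
}

icer_at <- function(spec, param, value) {
  fit <- cea(set_param(spec, param, value))
  fit$comparison$icer
}

#' One-way threshold search
#'
#' Finds the value of a single parameter (all others at base case) at
#' which the ICER equals the willingness-to-pay threshold, by bisection on
#' the incremental net monetary benefit (whose root coincides with
#' ICER = wtp and which is monotone in every supported parameter). The
#' search requires the NMB to change sign between the bounds.
#'
#' @param spec a [model_spec()].
#' @param param a parameter path (see [param_dist()]).
#' @param wtp willingness-to-pay in US$/QALY.
#' @param lower,upper search bounds; defaults depend on the parameter
#'   (costs: 0 to 10x base; probabilities/utilities: almost all of
#'   \[0, 1\]).
#' @param tol relative bisection tolerance on the parameter.
#' @return a list of class `"threshold_result"` with `param`, `wtp`,
#'   `threshold`, `direction` (`"minimum"` if NMB increases in the
#'   parameter, `"maximum"` otherwise) and `icer_check`, the ICER
#'   re-evaluated at the returned value.
#' @export
#' @examples
#' spec <- base_case_spec(synth_life_table())
#' one_way_threshold(spec, "c_radiotherapy_a", wtp = 30828)
one_way_threshold <- function(spec, param, wtp, lower = NULL, upper = NULL,
                              tol = 1e-6) {
  stopifnot(inherits(spec, "model_spec"), wtp > 0)
  param <- match.arg(param, .param_paths)
  if (is.null(lower) || is.null(upper)) {
    base <- coef(cea(spec, wtp))[[param]]
    if (startsWith(param, "c_")) {
      if (is.null(lower)) lower <- 0
      if (is.null(upper)) upper <- 10 * max(base, 1)
    } else {
      if (is.null(lower)) lower <- 1e-6
      if (is.null(upper)) upper <- 1 - 1e-6
    }
  }
  nmb_at <- function(v) {
    fit <- cea(set_param(spec, param, v), wtp)
    fit$nmb
  }
  f_lo <- nmb_at(lower); f_hi <- nmb_at(upper)
  if (!is.finite(f_lo) || !is.finite(f_hi) || sign(f_lo) == sign(f_hi))
    stop("no-threshold-in-range: NMB does not change sign over [",
         lower, ", ", upper, "]")
  lo <- lower; hi <- upper
  repeat {
    mid <- (lo + hi) / 2
    if ((hi - lo) <= tol * max(abs(mid), tol)) break
    if (sign(nmb_at(mid)) == sign(f_lo)) {
      lo <- mid
    } else {
      hi <- mid
    }
  }
  thr <- (lo + hi) / 2
  structure(list(param = param, wtp = wtp, threshold = thr,
                 direction = if (f_lo < 0) "minimum" else "maximum",
                 icer_check = icer_at(spec, param, thr)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Threshold for %s at WTP $%s/QALY: %s value %.6g (ICER there $%.1f)\n",
              x$param, format(x$wtp, big.mark = ","), x$direction,
              x$threshold, x$icer_check))
  invisible(x)
}

#' Tornado analysis (one-way ICER ranges)
#'
#' Sets each uncertain parameter in turn to the endpoints of its 90%
#' interval, all other parameters at base case, and records the resulting
#' ICERs. Entries are returned sorted by descending spread
#' `|icer_high - icer_low|`.
#'
#' @param spec a [model_spec()].
#' @param distributions list of [param_dist()]; defaults to
#'   [base_case_distributions()].
#' @param wtp willingness-to-pay (carried through to the output for
#'   reference; the ICER itself does not depend on it).
#' @return a data frame of class `"tornado"` with columns `param`, `low`,
#'   `high`, `icer_low`, `icer_high`, `spread`.
#' @export
tornado <- function(spec, distributions = base_case_distributions(),
                    wtp = 30828) {
  stopifnot(inherits(spec, "model_spec"), length(distributions) >= 1)
  rows <- lapply(distributions, function(d) {
    data.frame(param = d$param, low = d$ci90[1], high = d$ci90[2],
               icer_low = icer_at(spec, d$param, d$ci90[1]),
               icer_high = icer_at(spec, d$param, d$ci90[2]))
  })
  out <- do.call(rbind, rows)
  out$spread <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "wtp") <- wtp
  class(out) <- c("tornado", "data.frame")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Samples every distributed parameter jointly and independently, reruns
#' both strategies per draw (via a vectorised cohort engine identical to
#' [run_cohort()]), and records the incremental cost, incremental
#' effectiveness and net monetary benefit of strategy a versus b.
#' `fraction_favoring_a` is the share of iterations with NMB > 0 at the
#' threshold (ties count as not favoring). Parameters are sampled in the
#' order of `distributions` from a single RNG stream, so a fixed seed
#' reproduces the result bit-identically.
#'
#' @param spec a [model_spec()].
#' @param distributions list of [param_dist()].
#' @param n number of iterations.
#' @param seed integer RNG seed.
#' @param wtp willingness-to-pay in US$/QALY.
#' @return an object of class `"psa_result"`: list with `draws` (data
#'   frame: iteration, delta_cost, delta_qaly, nmb), `fraction_favoring_a`,
#'   `n`, `seed`, `wtp` and `param_summary` (per-parameter draw
#'   percentiles).
#' @export
run_psa <- function(spec, distributions = base_case_distributions(),
                    n = 50000, seed = 1, wtp = 30828) {
  stopifnot(inherits(spec, "model_spec"), n >= 1)
  set.seed(seed)
  samplers <- lapply(distributions, fit_distribution)
  draws <- lapply(samplers, function(s) s(n))
  names(draws) <- vapply(distributions, `[[`, "", "param")
  get <- function(path, default) if (path %in% names(draws)) draws[[path]]
    else default
  s <- spec
  u_wc <- get("u_with_cancer", s$disease$u_with_cancer)
  # the first-year utility is tied to the with-cancer state's value
  u_first <- if ("u_with_cancer" %in% names(draws)) u_wc
    else s$disease$u_first_year
  shared <- list(p_cancer_death = get("p_cancer_death", s$disease$p_cancer_death),
                 u_no_cancer = get("u_no_cancer", s$disease$u_no_cancer),
                 u_with_cancer = u_wc, u_first_year = u_first,
                 c_followup = get("c_followup", s$disease$c_followup),
                 c_palliative = get("c_palliative", s$disease$c_palliative))
  tot_a <- do.call(cohort_totals_vec, c(list(
    spec = s, p_eradicate = get("p_eradicate_a", s$strategy_a$p_eradicate),
    c_rt = get("c_radiotherapy_a", s$strategy_a$c_radiotherapy),
    c_chemo = get("c_chemo", s$strategy_a$c_chemo)), shared))
  tot_b <- do.call(cohort_totals_vec, c(list(
    spec = s, p_eradicate = get("p_eradicate_b", s$strategy_b$p_eradicate),
    c_rt = get("c_radiotherapy_b", s$strategy_b$c_radiotherapy),
    c_chemo = get("c_chemo", s$strategy_b$c_chemo)), shared))
  dc <- tot_a$cost - tot_b$cost
  de <- tot_a$qaly - tot_b$qaly
  nmb <- wtp * de - dc
  structure(list(
    draws = data.frame(iteration = seq_len(n), delta_cost = dc,
                       delta_qaly = de, nmb = nmb),
    fraction_favoring_a = mean(nmb > 0),
    n = n, seed = seed, wtp = wtp,
    param_summary = t(vapply(draws, stats::quantile,
                             numeric(5), probs = c(0.05, 0.25, 0.5, 0.75, 0.95))),
    param_draws = draws),
    class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d), WTP $%s/QALY\n", x$n, x$seed,
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  mean dC = $%.1f, mean dE = %.2f QALYs\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qaly)))
  cat(sprintf("  fraction favoring %s: %.1f%%\n", "strategy a",
              100 * x$fraction_favoring_a))
  invisible(x)
}

#' Age-stratified incremental cost-effectiveness
#'
#' Re-fits the comparison with the starting age set to each value and the
#' horizon running to the life-expectancy endpoint (`endpoint_age - age`),
#' all other parameters at base case.
#'
#' @param spec a [model_spec()].
#' @param ages integer starting ages, each below the endpoint age.
#' @return a data frame with columns `age`, `delta_cost`, `delta_qaly`,
#'   `icer`.
#' @export
age_stratified_icer <- function(spec, ages = seq(0, 70, by = 10)) {
  stopifnot(inherits(spec, "model_spec"))
  endpoint <- spec$settings$endpoint_age
  if (any(ages >= endpoint))
    stop("invalid-age: ages must be below the endpoint age (", endpoint, ")")
  rows <- lapply(ages, function(a) {
    s <- spec
    s$settings <- run_settings(start_age = a, horizon = NULL,
                               discount_rate = spec$settings$discount_rate,
                               endpoint_age = endpoint)
    cmp <- cea(s)$comparison
    data.frame(age = a, delta_cost = cmp$delta_cost,
               delta_qaly = cmp$delta_effect, icer = cmp$icer)
  })
  do.call(rbind, rows)
}

#' Oldest starting age at which strategy a is cost-effective
#'
#' Scans integer starting ages from 0 to `endpoint_age - 1` and returns
#' the largest age whose base-case ICER is at or below the threshold
#' (with positive incremental effectiveness).
#'
#' @param spec a [model_spec()].
#' @param wtp willingness-to-pay in US$/QALY.
#' @return integer age in years.
#' @export
age_threshold <- function(spec, wtp = 30828) {
  stopifnot(inherits(spec, "model_spec"))
  ages <- 0:(spec$settings$endpoint_age - 1)
  strat <- age_stratified_icer(spec, ages)
  ok <- strat$delta_qaly > 0 & strat$icer <= wtp
  if (!any(ok))
    stop("no-crossing: not cost-effective at any starting age (direction: above wtp everywhere)")
  if (all(ok))
    stop("no-crossing: cost-effective at every starting age (direction: below wtp everywhere)")
  max(strat$age[ok])
}
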