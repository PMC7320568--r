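#' Treatment strategy parameters
#'
#' One arm of the comparison: the probability that radiotherapy eradicates
#' the tumour (which fixes the initial Markov state distribution) and the
#' one-time treatment costs charged at cycle 0.
#'
#' @param name strategy label, e.g. `"IMPT"`.
#' @param p_eradicate probability in \[0, 1\] that treatment achieves
#'   complete response.
#' @param c_radiotherapy one-time radiotherapy cost in US$.
#' @param c_chemo one-time concurrent-chemotherapy cost in US$ (charged in
#'   both arms, so it cancels in the incremental cost).
#' @return an object of class `"strategy_params"`.
#' @export
strategy_params <- function(name, p_eradicate, c_radiotherapy, c_chemo = 5000) {
  if (!is.numeric(p_eradicate) || length(p_eradicate) != 1L ||
      !is.finite(p_eradicate) || p_eradicate < 0 || p_eradicate > 1)
    stop("invalid-spec: p_eradicate must be a probability in [0,1]")
  if (!is.finite(c_radiotherapy) || c_radiotherapy < 0 ||
      !is.finite(c_chemo) || c_chemo < 0)
    stop("invalid-spec: costs must be finite and >= 0")
  structure(list(name = as.character(name)[1],
                 p_eradicate = p_eradicate,
                 c_radiotherapy = as.numeric(c_radiotherapy),
                 c_chemo = as.numeric(c_chemo)),
            class = "strategy_params")
}

#' Relapse schedule
#'
#' Piecewise-constant annual probability of relapse (transition from
#' "no cancer" to "alive with cancer") by year since radiotherapy.
#' Intervals must be ordered and disjoint; years not covered by any
#' interval have relapse probability 0.
#'
#' @param from_year,to_year integer year bounds (inclusive) of each
#'   interval, counted from 1 = first year after radiotherapy.
#' @param prob annual relapse probability on each interval.
#' @return a data frame of class `"relapse_schedule"`.
#' @export
relapse_schedule <- function(from_year, to_year, prob) {
  stopifnot(length(from_year) == length(to_year),
            length(prob) == length(from_year))
  if (length(prob) > 0) {
    if (any(prob < 0 | prob > 1))
      stop("invalid-spec: relapse probabilities must lie in [0,1]")
    if (any(from_year < 1) || any(to_year < from_year))
      stop("invalid-spec: malformed relapse interval")
    o <- order(from_year)
    from_year <- from_year[o]; to_year <- to_year[o]; prob <- prob[o]
    if (length(from_year) > 1 &&
        any(from_year[-1] <= to_year[-length(to_year)]))
      stop("invalid-spec: relapse intervals overlap")
  }
  structure(data.frame(from_year = as.integer(from_year),
                       to_year = as.integer(to_year),
                       prob = as.numeric(prob)),
            class = c("relapse_schedule", "data.frame"))
}

#' Annual relapse probability at a given cycle
#'
#' @param schedule a [relapse_schedule()].
#' @param cycle cycle index (year since radiotherapy), vectorised.
#' @return numeric vector of annual relapse probabilities (0 outside all
#'   intervals).
#' @export
relapse_prob <- function(schedule, cycle) {
  stopifnot(inherits(schedule, "relapse_schedule"))
  vapply(cycle, function(t) {
    hit <- schedule$from_year <= t & t <= schedule$to_year
    if (any(hit)) schedule$prob[which(hit)[1L]] else 0
  }, numeric(1))
}

#' Disease natural-history, utility and yearly-cost parameters
#'
#' Shared between the two strategies: the relapse schedule, the annual
#' cancer-specific death probability from the "alive with cancer" state,
#' health-state utility values (HSUV, 0 = death, 1 = full health) and the
#' yearly follow-up and palliative-therapy costs.
#'
#' @param schedule a [relapse_schedule()].
#' @param p_cancer_death annual probability of cancer death from the
#'   "alive with cancer" state.
#' @param u_no_cancer HSUV of the "no cancer" state (from the second year).
#' @param u_with_cancer HSUV of the "alive with cancer" state.
#' @param u_first_year HSUV applied to both alive states during the first
#'   year after radiotherapy (treatment disutility).
#' @param u_death HSUV of death (fixed 0).
#' @param c_followup follow-up cost in US$/year, accrued by every alive
#'   state.
#' @param c_palliative palliative-therapy cost in US$/year, accrued by the
#'   "alive with cancer" state on top of follow-up.
#' @return an object of class `"disease_params"`.
#' @export
disease_params <- function(schedule = relapse_schedule(c(1, 4, 6), c(3, 5, 10),
                                                       c(0.1, 0.05, 0.01)),
                           p_cancer_death = 0.3,
                           u_no_cancer = 0.94, u_with_cancer = 0.47,
                           u_first_year = 0.47, u_death = 0,
                           c_followup = 1000, c_palliative = 5000) {
  probs <- c(p_cancer_death = p_cancer_death)
  utils_ <- c(u_no_cancer = u_no_cancer, u_with_cancer = u_with_cancer,
              u_first_year = u_first_year, u_death = u_death)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stop("invalid-spec: p_cancer_death must be a probability in [0,1]")
  if (any(!is.finite(utils_)) || any(utils_ < 0 | utils_ > 1))
    stop("invalid-spec: utilities must lie in [0,1]")
  if (!is.finite(c_followup) || c_followup < 0 ||
      !is.finite(c_palliative) || c_palliative < 0)
    stop("invalid-spec: yearly costs must be finite and >= 0")
  structure(list(schedule = schedule, p_cancer_death = p_cancer_death,
                 u_no_cancer = u_no_cancer, u_with_cancer = u_with_cancer,
                 u_first_year = u_first_year, u_death = u_death,
                 c_followup = as.numeric(c_followup),
                 c_palliative = as.numeric(c_palliative)),
            class = "disease_params")
}

#' Cohort run settings
#'
#' @param start_age age in years at the end of radiotherapy (cycle 0).
#' @param horizon number of annual cycles; `NULL` means
#'   `endpoint_age - start_age` (run to the life-expectancy endpoint). If
#'   `start_age >= endpoint_age` the horizon is forced to 1 cycle with a
#'   warning.
#' @param discount_rate annual discount rate applied to both costs and
#'   QALYs.
#' @param endpoint_age life-expectancy endpoint used when `horizon` is
#'   `NULL`.
#' @return an object of class `"run_settings"`.
#' @export
run_settings <- function(start_age = 47, horizon = NULL,
                         discount_rate = 0.03, endpoint_age = 77) {
  if (!is.finite(start_age) || start_age < 0)
    stop("invalid-spec: start_age must be >= 0")
  if (!is.finite(discount_rate) || discount_rate < 0 || discount_rate >= 1)
    stop("invalid-spec: discount_rate must lie in [0,1)")
  if (is.null(horizon)) {
    horizon <- endpoint_age - start_age
    if (horizon < 1) {
      warning("start_age at or beyond the endpoint; forcing horizon = 1")
      horizon <- 1
    }
  }
  horizon <- as.integer(horizon)
  if (horizon < 1) stop("invalid-spec: horizon must be >= 1")
  structure(list(start_age = as.numeric(start_age), horizon = horizon,
                 cycle_length = 1, discount_rate = discount_rate,
                 endpoint_age = endpoint_age),
            class = "run_settings")
}

#' Full model specification for one two-strategy comparison
#'
#' Bundles the two treatment strategies with the shared disease parameters,
#' run settings and background-mortality life table. All clinical outcomes
#' other than tumour eradication (and the radiotherapy cost) are identical
#' between arms.
#'
#' @param strategy_a,strategy_b [strategy_params()] for the two arms
#'   (conventionally a = the new technology, b = the comparator).
#' @param disease a [disease_params()].
#' @param settings a [run_settings()].
#' @param life_table a [life_table()].
#' @return an object of class `"model_spec"`.
#' @export
model_spec <- function(strategy_a, strategy_b, disease = disease_params(),
                       settings = run_settings(),
                       life_table = us_life_table_2016()) {
  stopifnot(inherits(strategy_a, "strategy_params"),
            inherits(strategy_b, "strategy_params"),
            inherits(disease, "disease_params"),
            inherits(settings, "run_settings"),
            inherits(life_table, "life_table"))
  structure(list(strategy_a = strategy_a, strategy_b = strategy_b,
                 disease = disease, settings = settings,
                 life_table = life_table),
            class = "model_spec")
}

#' The base-case model specification
#'
#' The published base case: a 47-year-old patient, 30 annual cycles (to the
#' 77-year life-expectancy endpoint), 3% discounting, IMPT
#' (p_eradicate = 0.9, $50,000) versus IMRT (p_eradicate = 0.73, $12,000),
#' shared chemotherapy ($5,000), follow-up ($1,000/yr) and palliative
#' therapy ($5,000/yr), utilities 0.94 / 0.47 (0.47 in the first year for
#' both alive states), annual cancer death probability 0.3 and relapse
#' probabilities 0.1 (years 1-3), 0.05 (4-5), 0.01 (6-10), 0 thereafter.
#'
#' @param life_table background mortality; defaults to the vendored
#'   sex-combined 2016 US table.
#' @param start_age base-case starting age.
#' @return a [model_spec()].
#' @export
#' @examples
#' fit <- cea(base_case_spec())
#' fit
base_case_spec <- function(life_table = us_life_table_2016(),
                           start_age = 47) {
  model_spec(
    strategy_a = strategy_params("IMPT", 0.9, 50000, 5000),
    strategy_b = strategy_params("IMRT", 0.73, 12000, 5000),
    disease = disease_params(),
    settings = run_settings(start_age = start_age),
    life_table = life_table)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Markov cohort CEA specification\n")
  cat(sprintf("  A: %-6s p_eradicate=%.3f  c_rt=$%s  c_chemo=$%s\n",
              x$strategy_a$name, x$strategy_a$p_eradicate,
              format(x$strategy_a$c_radiotherapy, big.mark = ","),
              format(x$strategy_a$c_chemo, big.mark = ",")))
  cat(sprintf("  B: %-6s p_eradicate=%.3f  c_rt=$%s  c_chemo=$%s\n",
              x$strategy_b$name, x$strategy_b$p_eradicate,
              format(x$strategy_b$c_radiotherapy, big.mark = ","),
              format(x$strategy_b$c_chemo, big.mark = ",")))
  cat(sprintf("  start age %g, %d annual cycles, discount %.1f%%\n",
              x$settings$start_age, x$settings$horizon,
              100 * x$settings$discount_rate))
  cat(sprintf("  life table: %s\n", attr(x$life_table, "provenance")))
  invisible(x)
}
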