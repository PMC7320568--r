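#' Read a model configuration from YAML
#'
#' The configuration holds everything needed to reproduce an analysis:
#' the two strategies, the shared disease parameters, run settings, the
#' PSA parameter distributions and the willingness-to-pay thresholds. A
#' bundled example (`system.file("extdata", "base_case.yaml",
#' package = "pbtcea")`) reproduces the published base case. Defaults
#' when keys are omitted: discount rate 0.03, cycle length 1 year,
#' `horizon: auto` (endpoint age minus starting age, endpoint default
#' 77), WTP 30,828 $/QALY, PSA 50,000 iterations.
#'
#' @param path path to a YAML configuration.
#' @param life_table a [life_table()] to attach; default the vendored
#'   2016 US table.
#' @return a list of class `"cea_config"` with elements `spec`
#'   ([model_spec()]), `distributions` (list of [param_dist()]), `wtp`
#'   (numeric vector) and `psa_n`.
#' @export
read_model_spec <- function(path, life_table = us_life_table_2016()) {
  raw <- yaml::read_yaml(path)
  need <- function(x, key, where) {
    if (is.null(x[[key]]))
      stop("schema error: missing required key '", where, key, "'")
    x[[key]]
  }
  strategies <- need(raw, "strategies", "")
  if (length(strategies) != 2)
    stop("schema error: 'strategies' must list exactly two strategies")
  mk_strategy <- function(s, idx) {
    where <- paste0("strategies[", idx, "].")
    p <- need(s, "p_eradicate", where)
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("schema error: '", where, "p_eradicate' outside [0,1]")
    strategy_params(need(s, "name", where), p,
                    need(s, "cost_radiotherapy", where),
                    need(s, "cost_chemo", where))
  }
  dz_raw <- need(raw, "disease", "")
  sched_raw <- need(dz_raw, "relapse_schedule", "disease.")
  sched <- relapse_schedule(
    from_year = vapply(sched_raw, function(x)
      need(x, "from_year", "disease.relapse_schedule."), numeric(1)),
    to_year = vapply(sched_raw, function(x)
      need(x, "to_year", "disease.relapse_schedule."), numeric(1)),
    prob = vapply(sched_raw, function(x)
      need(x, "prob", "disease.relapse_schedule."), numeric(1)))
  ut <- need(dz_raw, "utilities", "disease.")
  co <- need(dz_raw, "costs", "disease.")
  disease <- disease_params(
    schedule = sched,
    p_cancer_death = need(dz_raw, "p_cancer_death", "disease."),
    u_no_cancer = need(ut, "no_cancer", "disease.utilities."),
    u_with_cancer = need(ut, "with_cancer", "disease.utilities."),
    u_first_year = need(ut, "first_year", "disease.utilities."),
    u_death = if (is.null(ut$death)) 0 else ut$death,
    c_followup = need(co, "followup_per_year", "disease.costs."),
    c_palliative = need(co, "palliative_per_year", "disease.costs."))
  st_raw <- need(raw, "settings", "")
  horizon <- st_raw$horizon
  if (is.null(horizon) || identical(horizon, "auto")) horizon <- NULL
  settings <- run_settings(
    start_age = need(st_raw, "start_age", "settings."),
    horizon = horizon,
    discount_rate = if (is.null(st_raw$discount_rate)) 0.03
      else st_raw$discount_rate,
    endpoint_age = if (is.null(st_raw$life_expectancy_endpoint)) 77
      else st_raw$life_expectancy_endpoint)
  spec <- model_spec(mk_strategy(strategies[[1]], 1),
                     mk_strategy(strategies[[2]], 2),
                     disease, settings, life_table)
  dists <- lapply(raw$distributions, function(d) {
    param_dist(need(d, "param", "distributions."),
               need(d, "kind", "distributions."),
               need(d, "mean", "distributions."),
               unlist(need(d, "ci90", "distributions.")))
  })
  structure(list(spec = spec, distributions = dists,
                 wtp = if (is.null(raw$wtp)) 30828 else unlist(raw$wtp),
                 psa_n = if (is.null(raw$psa$n_iterations)) 50000
                   else raw$psa$n_iterations),
            class = "cea_config")
}

#' Serialize a configuration back to YAML
#'
#' Inverse of [read_model_spec()] (up to the attached life table, which
#' travels separately as CSV): parse, serialize, parse is idempotent.
#'
#' @param config a `"cea_config"` from [read_model_spec()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(config, path) {
  stopifnot(inherits(config, "cea_config"))
  spec <- config$spec
  as_strategy <- function(s) list(name = s$name, p_eradicate = s$p_eradicate,
                                  cost_radiotherapy = s$c_radiotherapy,
                                  cost_chemo = s$c_chemo)
  sched <- lapply(seq_len(nrow(spec$disease$schedule)), function(i)
    list(from_year = spec$disease$schedule$from_year[i],
         to_year = spec$disease$schedule$to_year[i],
         prob = spec$disease$schedule$prob[i]))
  out <- list(
    strategies = list(as_strategy(spec$strategy_a),
                      as_strategy(spec$strategy_b)),
    disease = list(
      relapse_schedule = sched,
      p_cancer_death = spec$disease$p_cancer_death,
      utilities = list(no_cancer = spec$disease$u_no_cancer,
                       with_cancer = spec$disease$u_with_cancer,
                       first_year = spec$disease$u_first_year,
                       death = spec$disease$u_death),
      costs = list(followup_per_year = spec$disease$c_followup,
                   palliative_per_year = spec$disease$c_palliative)),
    settings = list(start_age = spec$settings$start_age,
                    horizon = spec$settings$horizon,
                    discount_rate = spec$settings$discount_rate,
                    life_expectancy_endpoint = spec$settings$endpoint_age),
    wtp = config$wtp,
    psa = list(n_iterations = config$psa_n),
    distributions = lapply(config$distributions, function(d)
      list(param = d$param, kind = d$kind, mean = d$mean,
           ci90 = d$ci90)))
  yaml::write_yaml(out, path)
  invisible(path)
}
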