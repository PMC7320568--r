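#' Run one analysis stage end to end and write its outputs
#'
#' Thin orchestration over the package's analysis functions: reads the
#' YAML configuration (and optional life-table CSV), executes one command
#' and writes its outputs plus a run manifest JSON into `out_dir`.
#' Progress is logged to standard error via [message()] so file outputs
#' stay pipeable. Commands:
#' \describe{
#'   \item{run}{both cohort runs, trace CSVs and the comparison
#'     (`results.json`).}
#'   \item{psa}{probabilistic sensitivity analysis (`psa.csv`,
#'     `psa_summary.json`).}
#'   \item{tornado}{one-way ICER ranges (`tornado.csv`).}
#'   \item{threshold}{one-way threshold for `param`
#'     (`threshold_<param>.json`).}
#'   \item{age-strata}{age-stratified comparison (`age_strata.csv`).}
#'   \item{age-threshold}{oldest cost-effective starting age
#'     (`age_threshold.json`).}
#'   \item{microsim}{patient-level estimates for both arms
#'     (`microsim_a.json`, `microsim_b.json`).}
#'   \item{mc-selection}{paired Monte Carlo strategy selection
#'     (`mc_selection.json`).}
#'   \item{synth-lifetable}{write a synthetic Gompertz-Makeham life table
#'     (`synthetic_lifetable.csv`).}
#' }
#'
#' @param command one of the commands above.
#' @param config path to a YAML configuration ([read_model_spec()]).
#' @param out_dir output directory (created if missing).
#' @param lifetable optional path to a life-table CSV overriding the
#'   vendored table.
#' @param seed integer seed for the randomized commands.
#' @param wtp willingness-to-pay override; default the first configured
#'   threshold.
#' @param n iteration/patient count override for psa/microsim/
#'   mc-selection.
#' @param param parameter path for `threshold`.
#' @return the manifest, invisibly: list with `command`, `config`,
#'   `config_md5`, `life_table_provenance`, `seed`, `wtp`, `version` and
#'   `outputs` (paths written, all existing).
#' @export
run_pipeline <- function(command = c("run", "psa", "tornado", "threshold",
                                     "age-strata", "age-threshold",
                                     "microsim", "mc-selection",
                                     "synth-lifetable"),
                         config, out_dir = ".", lifetable = NULL,
                         seed = 1, wtp = NULL, n = NULL, param = NULL) {
  command <- match.arg(command)
  t0 <- Sys.time()
  lt <- if (is.null(lifetable)) us_life_table_2016()
    else read_life_table(lifetable)
  cfg <- read_model_spec(config, life_table = lt)
  if (is.null(wtp)) wtp <- cfg$wtp[1]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(out_dir, f)
  message(sprintf("[pbtcea] %s: config=%s seed=%d wtp=%s", command,
                  config, seed, format(wtp, big.mark = ",")))
  outputs <- character(0)
  spec <- cfg$spec
  if (command == "run") {
    fit <- cea(spec, wtp)
    write_trace(fit$result_a, out("trace_a.csv"))
    write_trace(fit$result_b, out("trace_b.csv"))
    jsonlite::write_json(list(
      strategy_a = list(name = fit$result_a$strategy,
                        total_cost = fit$result_a$total_cost,
                        total_qaly = fit$result_a$total_qaly),
      strategy_b = list(name = fit$result_b$strategy,
                        total_cost = fit$result_b$total_cost,
                        total_qaly = fit$result_b$total_qaly),
      comparison = list(delta_cost = fit$comparison$delta_cost,
                        delta_qaly = fit$comparison$delta_effect,
                        icer = fit$comparison$icer,
                        dominance = fit$comparison$dominance,
                        wtp = wtp, nmb = fit$nmb)),
      out("results.json"), auto_unbox = TRUE, digits = NA)
    outputs <- c(out("trace_a.csv"), out("trace_b.csv"),
                 out("results.json"))
  } else if (command == "psa") {
    psa <- run_psa(spec, cfg$distributions,
                   n = if (is.null(n)) cfg$psa_n else n,
                   seed = seed, wtp = wtp)
    utils::write.csv(psa$draws, out("psa.csv"), row.names = FALSE,
                     quote = FALSE)
    jsonlite::write_json(list(fraction_favoring = psa$fraction_favoring_a,
                              n = psa$n, seed = psa$seed, wtp = psa$wtp),
                         out("psa_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    outputs <- c(out("psa.csv"), out("psa_summary.json"))
  } else if (command == "tornado") {
    tor <- tornado(spec, cfg$distributions, wtp)
    utils::write.csv(as.data.frame(tor), out("tornado.csv"),
                     row.names = FALSE, quote = FALSE)
    outputs <- out("tornado.csv")
  } else if (command == "threshold") {
    if (is.null(param)) stop("schema error: 'threshold' needs --param")
    thr <- one_way_threshold(spec, param, wtp)
    jsonlite::write_json(list(parameter = thr$param, wtp = thr$wtp,
                              threshold = thr$threshold,
                              direction = thr$direction,
                              icer_check = thr$icer_check),
                         out(paste0("threshold_", param, ".json")),
                         auto_unbox = TRUE, digits = NA)
    outputs <- out(paste0("threshold_", param, ".json"))
  } else if (command == "age-strata") {
    strat <- age_stratified_icer(spec)
    utils::write.csv(strat, out("age_strata.csv"), row.names = FALSE,
                     quote = FALSE)
    outputs <- out("age_strata.csv")
  } else if (command == "age-threshold") {
    thr <- age_threshold(spec, wtp)
    jsonlite::write_json(list(wtp = wtp, age_threshold = thr),
                         out("age_threshold.json"), auto_unbox = TRUE,
                         digits = NA)
    outputs <- out("age_threshold.json")
  } else if (command == "microsim") {
    n_pat <- if (is.null(n)) 100000 else n
    est_a <- simulate_patients(spec$strategy_a, spec, n_pat, seed = seed)
    est_b <- simulate_patients(spec$strategy_b, spec, n_pat,
                               seed = seed + 1)
    write_microsim_summary(est_a, out("microsim_a.json"))
    write_microsim_summary(est_b, out("microsim_b.json"))
    outputs <- c(out("microsim_a.json"), out("microsim_b.json"))
  } else if (command == "mc-selection") {
    mc <- mc_strategy_selection(spec, n = if (is.null(n)) 50000 else n,
                                seed = seed, wtp = wtp)
    jsonlite::write_json(list(fraction_favoring = mc$fraction_favoring_a,
                              n = mc$n, seed = mc$seed, wtp = mc$wtp),
                         out("mc_selection.json"), auto_unbox = TRUE,
                         digits = NA)
    outputs <- out("mc_selection.json")
  } else if (command == "synth-lifetable") {
    write_life_table(synth_life_table(), out("synthetic_lifetable.csv"))
    outputs <- out("synthetic_lifetable.csv")
  }
  manifest <- list(command = command, config = config,
                   config_md5 = unname(tools::md5sum(config)),
                   life_table_provenance = attr(lt, "provenance"),
                   seed = seed, wtp = wtp,
                   version = as.character(utils::packageVersion("pbtcea")),
                   outputs = outputs)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  message(sprintf("[pbtcea] done in %.2fs; %d output(s) + manifest",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  length(outputs)))
  invisible(manifest)
}
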