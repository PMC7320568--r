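#' Fit the two-strategy Markov cohort cost-effectiveness model
#'
#' Runs the deterministic cohort trace for both strategies of a
#' [model_spec()] and computes the incremental comparison (a minus b):
#' incremental cost, incremental effectiveness (QALYs), the incremental
#' cost-effectiveness ratio ICER = dC / dE, and the net monetary benefit
#' at the willingness-to-pay threshold.
#'
#' @param spec a [model_spec()].
#' @param wtp willingness-to-pay threshold in US$/QALY (default three
#'   times the 2019 Chinese GDP per capita, $30,828/QALY).
#' @return an object of class `"cea"`: list with `result_a`, `result_b`
#'   ([run_cohort()] results), `comparison` (see [compare()]), `wtp`,
#'   `nmb` and `spec`.
#' @seealso [compare()], [net_monetary_benefit()], [run_psa()],
#'   [tornado()], [one_way_threshold()]
#' @export
#' @examples
#' fit <- cea(base_case_spec(synth_life_table()))
#' summary(fit)
cea <- function(spec, wtp = 30828) {
  stopifnot(inherits(spec, "model_spec"), is.finite(wtp), wtp > 0)
  ra <- run_cohort(spec$strategy_a, spec)
  rb <- run_cohort(spec$strategy_b, spec)
  cmp <- compare(ra, rb)
  structure(list(result_a = ra, result_b = rb, comparison = cmp,
                 wtp = wtp, nmb = net_monetary_benefit(cmp, wtp),
                 spec = spec),
            class = "cea")
}

#' Incremental comparison of two cohort runs
#'
#' Deltas are strategy a minus strategy b. The ICER is undefined (`NA`)
#' when the effectiveness difference is zero. Dominance is flagged when
#' one strategy is at least as cheap and at least as effective, with at
#' least one strict inequality.
#'
#' @param result_a,result_b [run_cohort()] results sharing settings.
#' @return an object of class `"comparison"`: list with `delta_cost`,
#'   `delta_effect`, `icer` and `dominance` (one of `"none"`,
#'   `"a_dominates"`, `"b_dominates"`, `"tie"`).
#' @export
compare <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "run_result"), inherits(result_b, "run_result"))
  dc <- result_a$total_cost - result_b$total_cost
  de <- result_a$total_qaly - result_b$total_qaly
  dominance <- if (dc == 0 && de == 0) "tie"
  else if (dc <= 0 && de >= 0) "a_dominates"
  else if (dc >= 0 && de <= 0) "b_dominates"
  else "none"
  structure(list(delta_cost = dc, delta_effect = de,
                 icer = if (de != 0) dc / de else NA_real_,
                 dominance = dominance,
                 name_a = result_a$strategy, name_b = result_b$strategy),
            class = "comparison")
}

#' @export
print.comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: dC = $%.1f, dE = %.2f QALYs", x$name_a, x$name_b,
              x$delta_cost, x$delta_effect))
  if (is.na(x$icer)) cat(", ICER undefined") else
    cat(sprintf(", ICER = $%.1f/QALY", x$icer))
  if (x$dominance != "none") cat(" [", x$dominance, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Incremental net monetary benefit
#'
#' `NMB = wtp * delta_effect - delta_cost`; positive means strategy a is
#' cost-effective relative to b at the threshold (equivalently, for
#' `delta_effect > 0`, ICER < wtp).
#'
#' @param comparison a [compare()] result.
#' @param wtp willingness-to-pay in US$/QALY.
#' @return net monetary benefit in US$.
#' @export
net_monetary_benefit <- function(comparison, wtp) {
  stopifnot(inherits(comparison, "comparison"))
  wtp * comparison$delta_effect - comparison$delta_cost
}

#' @export
print.cea <- function(x, ...) {
  cmp <- x$comparison
  cat("Markov cohort cost-effectiveness analysis\n")
  cat(sprintf("  %-6s $%12.1f  %6.2f QALYs\n", x$result_a$strategy,
              x$result_a$total_cost, x$result_a$total_qaly))
  cat(sprintf("  %-6s $%12.1f  %6.2f QALYs\n", x$result_b$strategy,
              x$result_b$total_cost, x$result_b$total_qaly))
  cat(sprintf("  dC = $%.1f, dE = %.2f QALYs, ICER = %s\n",
              cmp$delta_cost, cmp$delta_effect,
              if (is.na(cmp$icer)) "undefined"
              else sprintf("$%.1f/QALY", cmp$icer)))
  cat(sprintf("  at WTP $%s/QALY: NMB = $%.1f (%s)\n",
              format(x$wtp, big.mark = ","), x$nmb,
              if (x$nmb > 0) "cost-effective" else "not cost-effective"))
  invisible(x)
}

#' @export
summary.cea <- function(object, years = c(2, 5, 10), ...) {
  years <- years[years <= object$spec$settings$horizon]
  os <- rbind(overall_survival(object$result_a, years),
              overall_survival(object$result_b, years))
  dimnames(os) <- list(c(object$result_a$strategy,
                         object$result_b$strategy),
                       paste0("OS", years, "y"))
  out <- list(cea = object, os = os)
  class(out) <- "summary.cea"
  out
}

#' @export
print.summary.cea <- function(x, ...) {
  print(x$cea)
  cat("Overall survival (%):\n")
  print(round(100 * x$os, 1))
  invisible(x)
}

#' @export
coef.cea <- function(object, ...) {
  s <- object$spec
  c(p_eradicate_a = s$strategy_a$p_eradicate,
    p_eradicate_b = s$strategy_b$p_eradicate,
    c_radiotherapy_a = s$strategy_a$c_radiotherapy,
    c_radiotherapy_b = s$strategy_b$c_radiotherapy,
    c_chemo = s$strategy_a$c_chemo,
    c_followup = s$disease$c_followup,
    c_palliative = s$disease$c_palliative,
    u_no_cancer = s$disease$u_no_cancer,
    u_with_cancer = s$disease$u_with_cancer,
    p_cancer_death = s$disease$p_cancer_death,
    discount_rate = s$settings$discount_rate)
}

#' Plot overall-survival curves of a fitted comparison
#'
#' @param x a [cea()] object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cea <- function(x, ...) {
  t <- 0:x$spec$settings$horizon
  graphics::matplot(t, cbind(x$result_a$os_curve, x$result_b$os_curve),
                    type = "s", lty = 1, lwd = 2, col = c("firebrick", "navy"),
                    xlab = "Years since radiotherapy",
                    ylab = "Overall survival", ylim = c(0, 1), ...)
  graphics::legend("topright", legend = c(x$result_a$strategy,
                                          x$result_b$strategy),
                   col = c("firebrick", "navy"), lwd = 2, bty = "n")
  invisible(x)
}

#' Patient-level replication of a fitted comparison
#'
#' Draws `nsim` individual trajectories per arm with the microsimulation
#' engine (see [simulate_patients()]) and returns both arms' estimates;
#' a patient-level cross-check of the deterministic cohort totals.
#'
#' @param object a [cea()] object.
#' @param nsim number of patients per arm.
#' @param seed RNG seed (integer) for reproducibility.
#' @param ... unused.
#' @return list with elements `a` and `b`, each a `microsim_estimate`.
#' @export
simulate.cea <- function(object, nsim = 10000, seed = NULL, ...) {
  list(a = simulate_patients(object$spec$strategy_a, object$spec, nsim,
                             seed = seed),
       b = simulate_patients(object$spec$strategy_b, object$spec, nsim,
                             seed = if (is.null(seed)) NULL else seed + 1))
}
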