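#' Pairwise incremental cost-effectiveness comparison
#'
#' Computes the incremental cost `ΔC = C2 - C1` and incremental effect
#' `ΔE = E2 - E1` of an intervention (2) against a comparator (1) and
#' classifies the result on the dominance lattice:
#' \itemize{
#'   \item `ΔC < 0` and `ΔE > 0`: `INTERVENTION_DOMINANT` (cheaper and
#'     more effective; no ICER is reported).
#'   \item `ΔC > 0` and `ΔE < 0`: `COMPARATOR_DOMINANT`.
#'   \item `|ΔE| < 1e-12`: `EQUAL_EFFECT_COST_MINIMIZATION`, ICER
#'     undefined (division guard).
#'   \item otherwise: `ICER_REPORTED` with `icer = ΔC / ΔE` (EUR per
#'     life year).
#' }
#'
#' @param intervention,comparator `strategy_outcome` objects computed on
#'   the identical cohort, horizon and discounting.
#' @return A list of class `cea_comparison` with `intervention`,
#'   `comparator`, `delta_cost`, `delta_effect`, `icer` (`NA` unless
#'   verdict is `ICER_REPORTED`) and `verdict`.
#' @export
compare_strategies <- function(intervention, comparator) {
  same <- isTRUE(all.equal(intervention$cohort_size, comparator$cohort_size)) &&
    isTRUE(all.equal(intervention$economics[c("discount_rate",
                                              "horizon_years",
                                              "half_cycle_correction")],
                     comparator$economics[c("discount_rate",
                                            "horizon_years",
                                            "half_cycle_correction")]))
  if (!same) {
    stop("outcomes were computed under different cohort/economic settings",
         call. = FALSE)
  }
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_ly - comparator$total_ly
  classify_icer(dc, de,
                intervention = intervention$strategy,
                comparator = comparator$strategy)
}

# Dominance classification on raw deltas (exported for synthetic use in
# the sensitivity module and tests).
classify_icer <- function(delta_cost, delta_effect,
                          intervention = "intervention",
                          comparator = "comparator", tol = 1e-12) {
  de <- if (abs(delta_effect) < tol) 0 else delta_effect
  if (de == 0) {
    verdict <- "EQUAL_EFFECT_COST_MINIMIZATION"
    icer <- NA_real_
  } else if (delta_cost < 0 && de > 0) {
    verdict <- "INTERVENTION_DOMINANT"
    icer <- NA_real_
  } else if (delta_cost > 0 && de < 0) {
    verdict <- "COMPARATOR_DOMINANT"
    icer <- NA_real_
  } else {
    verdict <- "ICER_REPORTED"
    icer <- delta_cost / de
  }
  structure(list(intervention = intervention, comparator = comparator,
                 delta_cost = delta_cost, delta_effect = delta_effect,
                 icer = icer, verdict = verdict),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  cat(sprintf("<cea_comparison> %s vs %s\n", x$intervention, x$comparator))
  cat(sprintf("  dCOST EUR %.2f, dLY %.4f\n", x$delta_cost, x$delta_effect))
  if (x$verdict == "ICER_REPORTED") {
    cat(sprintf("  ICER EUR %.2f per LY\n", x$icer))
  } else {
    cat(sprintf("  verdict: %s\n", x$verdict))
  }
  invisible(x)
}

#' Cost-effectiveness comparison table across strategies
#'
#' The first outcome is taken as the intervention and compared against
#' each of the others, mirroring the published comparison-table layout
#' (costs, life years, ΔCOST, ΔLY, ICER/dominance).
#'
#' @param outcomes A named or unnamed list of at least two
#'   `strategy_outcome` objects; the first is the intervention.
#' @return A data frame with one row per strategy and, for the
#'   comparators, incremental columns relative to the intervention.
#' @export
comparison_table <- function(outcomes) {
  if (length(outcomes) < 2) stop("need at least two strategies", call. = FALSE)
  intv <- outcomes[[1]]
  rows <- lapply(outcomes, function(o) {
    row <- data.frame(strategy = o$strategy, total_cost = o$total_cost,
                      total_ly = o$total_ly,
                      delta_cost = NA_real_, delta_ly = NA_real_,
                      icer = NA_real_, verdict = NA_character_,
                      stringsAsFactors = FALSE)
    if (!identical(o$strategy, intv$strategy)) {
      cmp <- compare_strategies(intv, o)
      row$delta_cost <- cmp$delta_cost
      row$delta_ly <- cmp$delta_effect
      row$icer <- cmp$icer
      row$verdict <- cmp$verdict
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
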