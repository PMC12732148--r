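#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the pairwise comparison with each uncertain parameter
#' set to the lower and upper end of its normalized interval, all other
#' parameters held at base values. Entries are ranked by descending
#' spread of the incremental net monetary benefit
#' `INMB = wtp * ΔE - ΔC` at a reference willingness-to-pay, because raw
#' ICERs flip sign across dominance regions and cannot be ranked;
#' `metric = "icer"` ranks by raw ICER spread instead (undefined ICERs
#' propagate as `NA` spreads, ranked last).
#'
#' @param params An `nstage_params` object (its `uncertainty` table
#'   defines which parameters are varied and over what interval).
#' @param lifetable A `lifetable`.
#' @param intervention,comparator Strategy names; default PET/CT vs CT.
#' @param wtp Reference willingness-to-pay in EUR per life year for the
#'   INMB ranking (default 27,117, a published supply-side estimate of
#'   the Greek threshold).
#' @param metric `"inmb"` (default) or `"icer"`.
#' @param ... Passed to [evaluate_strategy()] (toggles).
#' @return A data frame of class `tornado` sorted by descending
#'   `spread`, with columns `parameter_id`, `value_low`, `value_high`,
#'   `icer_at_low`, `icer_at_high`, `verdict_at_low`, `verdict_at_high`,
#'   `inmb_at_low`, `inmb_at_high`, `spread`.
#' @export
one_way_dsa <- function(params, lifetable = default_lifetable(),
                        intervention = "PETCT", comparator = "CT",
                        wtp = 27117, metric = c("inmb", "icer"), ...) {
  metric <- match.arg(metric)
  unc <- params$uncertainty[params$uncertainty$family != "fixed", ,
                           drop = FALSE]
  eval_pair <- function(p) {
    a <- evaluate_strategy(p, intervention, lifetable, ...)
    b <- evaluate_strategy(p, comparator, lifetable, ...)
    cmp <- compare_strategies(a, b)
    list(icer = cmp$icer, verdict = cmp$verdict,
         inmb = wtp * cmp$delta_effect - cmp$delta_cost)
  }
  rows <- lapply(seq_len(nrow(unc)), function(i) {
    row <- unc[i, ]
    b <- normalize_interval(row$mean, row$lower, row$upper, row$clerical)
    lo <- eval_pair(param_set(params, row$parameter_id, b[1]))
    hi <- eval_pair(param_set(params, row$parameter_id, b[2]))
    spread <- switch(metric,
                     inmb = abs(hi$inmb - lo$inmb),
                     icer = abs(hi$icer - lo$icer))
    data.frame(parameter_id = row$parameter_id,
               value_low = b[1], value_high = b[2],
               icer_at_low = lo$icer, icer_at_high = hi$icer,
               verdict_at_low = lo$verdict, verdict_at_high = hi$verdict,
               inmb_at_low = lo$inmb, inmb_at_high = hi$inmb,
               spread = spread, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$parameter_id, na.last = TRUE), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  out
}

#' Draw one parameter set for probabilistic sensitivity analysis
#'
#' Each parameter in the uncertainty table is replaced by one draw from
#' its fitted distribution (beta for probabilities, lognormal for costs,
#' uniform where specified); `fixed` parameters are untouched. Draws are
#' independent across parameters (no correlation structure; the
#' sensitivity and specificity of a modality are sampled independently).
#' Uses the current RNG stream — call `set.seed()` upstream for
#' reproducibility.
#'
#' @param params An `nstage_params` object.
#' @return A new `nstage_params` with sampled values.
#' @export
sample_parameter_set <- function(params) {
  unc <- params$uncertainty
  for (i in seq_len(nrow(unc))) {
    row <- unc[i, ]
    if (row$family == "fixed") next
    params <- param_set(params, row$parameter_id, draw_uncertain(row))
  }
  params
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of the parameter distributions through the
#' full model. Each draw samples one parameter set, evaluates every
#' strategy, and records costs and life years; pairwise incremental
#' clouds against the intervention give dominance probabilities and
#' cost-effectiveness acceptability curves (CEAC):
#' `p_dominant = P(ΔC < 0 and ΔE > 0)` and
#' `CEAC(λ) = P(λ ΔE - ΔC > 0)` over the willingness-to-pay grid.
#' Seeded and bit-for-bit reproducible at fixed `seed` and `n_draws`.
#'
#' @param params An `nstage_params` object.
#' @param lifetable A `lifetable`.
#' @param n_draws Number of Monte-Carlo draws (>= 1; default 1000).
#' @param seed Integer seed, recorded in the result.
#' @param wtp_grid Willingness-to-pay grid (EUR per LY) for the CEAC.
#' @param intervention Strategy compared against all others.
#' @param ... Passed to [evaluate_strategy()] (toggles).
#' @return A list of class `psa_result`: `n_draws`, `seed`, `draws` (a
#'   data frame of per-draw costs/LYs per strategy and pairwise
#'   deltas), `p_dominant` and `quadrants` per comparison, and `ceac`
#'   (long data frame of comparison, wtp, probability).
#' @export
run_psa <- function(params, lifetable = default_lifetable(),
                    n_draws = 1000, seed = 1L,
                    wtp_grid = seq(0, 200000, by = 5000),
                    intervention = "PETCT", ...) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  comparators <- setdiff(.STRATEGIES, intervention)
  set.seed(seed)
  draws <- vector("list", n_draws)
  for (k in seq_len(n_draws)) {
    sp <- sample_parameter_set(params)
    out <- lapply(.STRATEGIES, function(s)
      evaluate_strategy(sp, s, lifetable, ...))
    names(out) <- .STRATEGIES
    rec <- list(draw = k)
    for (s in .STRATEGIES) {
      rec[[paste0("cost_", s)]] <- out[[s]]$total_cost
      rec[[paste0("ly_", s)]] <- out[[s]]$total_ly
    }
    for (cp in comparators) {
      rec[[paste0("dcost_", intervention, "_vs_", cp)]] <-
        out[[intervention]]$total_cost - out[[cp]]$total_cost
      rec[[paste0("dly_", intervention, "_vs_", cp)]] <-
        out[[intervention]]$total_ly - out[[cp]]$total_ly
    }
    draws[[k]] <- as.data.frame(rec)
  }
  draws <- do.call(rbind, draws)
  p_dominant <- numeric(0)
  quadrants <- list()
  ceac <- list()
  for (cp in comparators) {
    key <- paste0(intervention, "_vs_", cp)
    dc <- draws[[paste0("dcost_", key)]]
    de <- draws[[paste0("dly_", key)]]
    p_dominant[key] <- mean(dc < 0 & de > 0)
    # exact partition of the incremental plane (boundary draws land in
    # the trade-off cells, so the four probabilities sum to 1)
    q <- c(dominant = mean(dc < 0 & de > 0),
           dominated = mean(dc > 0 & de < 0),
           tradeoff_ne = mean(dc >= 0 & de >= 0))
    quadrants[[key]] <- c(q, tradeoff_sw = 1 - sum(q))
    ceac[[key]] <- data.frame(
      comparison = key, wtp = wtp_grid,
      probability = vapply(wtp_grid, function(l) mean(l * de - dc > 0), 0)
    )
  }
  structure(list(n_draws = n_draws, seed = seed, intervention = intervention,
                 draws = draws, p_dominant = p_dominant,
                 quadrants = quadrants,
                 ceac = do.call(rbind, ceac)),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws, seed %d\n", x$n_draws, x$seed))
  for (key in names(x$p_dominant)) {
    cat(sprintf("  P(%s dominant) = %.1f%%\n",
                sub("_vs_", " vs ", key), 100 * x$p_dominant[key]))
  }
  invisible(x)
}
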