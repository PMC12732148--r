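#' Normalize a published uncertainty interval
#'
#' Several printed ranges in the source tariff/parameter table are
#' internally inconsistent (a lower bound above the upper bound, a bound
#' equal to the mean, or bounds evidently copied from an adjacent row).
#' The normalization rule: a consistent printed interval
#' (`lower <= mean <= upper`) is kept as printed. An inconsistent one is
#' replaced by the interval \[min, max\] over the set \{printed lower,
#' printed upper, mean - 10\% of mean, mean + 10\% of mean\}. Rows
#' flagged `clerical` (bounds plainly copied from another row) discard
#' the printed bounds entirely and use mean +/- 10\%. The +/- 10\%
#' envelope matches the half-width pattern of the uncorrupted rows.
#'
#' @param mean Published mean value.
#' @param lower,upper Published interval bounds (may be `NA`).
#' @param clerical Logical; `TRUE` when the printed bounds are a known
#'   clerical error.
#' @param rel Relative half-width of the fallback envelope (default 0.10).
#' @return Numeric vector `c(lower, upper)` with `lower <= mean <= upper`.
#' @export
normalize_interval <- function(mean, lower = NA, upper = NA,
                               clerical = FALSE, rel = 0.10) {
  stopifnot(is.finite(mean))
  envelope <- c(mean * (1 - rel), mean * (1 + rel))
  if (isTRUE(clerical) || (is.na(lower) && is.na(upper))) {
    return(range(envelope))
  }
  if (!is.na(lower) && !is.na(upper) && lower <= mean && mean <= upper) {
    return(c(lower, upper))
  }
  range(c(lower, upper, envelope), na.rm = TRUE)
}

#' Fit a beta distribution to a mean and 95\% interval
#'
#' Method-of-moments fit for probabilistic sensitivity analysis of
#' probability parameters. The interval is treated as a 95\% interval,
#' so the implied standard deviation is `(upper - lower) / 3.92`. The
#' fitted distribution reproduces the input mean exactly (to 1e-9).
#'
#' @param mean Mean probability, strictly inside (0, 1).
#' @param lower,upper Interval bounds with `lower <= mean <= upper`
#'   (normalize first with [normalize_interval()] if needed).
#' @return Named numeric vector `c(alpha = ..., beta = ...)`, both
#'   shapes strictly positive.
#' @examples
#' fit_beta_from_interval(0.5, 0.4, 0.6)  # symmetric: alpha == beta
#' @export
fit_beta_from_interval <- function(mean, lower, upper) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop("beta fit is degenerate for mean at or outside (0, 1); ",
         "use family = \"fixed\" instead", call. = FALSE)
  }
  stopifnot(lower <= mean, mean <= upper)
  sd <- (upper - lower) / 3.92
  if (sd == 0) {
    stop("zero-width interval; use family = \"fixed\" instead",
         call. = FALSE)
  }
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("implied variance ", signif(v, 4), " >= mean*(1-mean) = ",
         signif(mean * (1 - mean), 4), "; beta distribution infeasible",
         call. = FALSE)
  }
  k <- mean * (1 - mean) / v - 1
  c(alpha = mean * k, beta = (1 - mean) * k)
}

#' Fit a lognormal distribution to a mean and 95\% interval
#'
#' Moment-matched on the natural (arithmetic) scale: with
#' `sd = (upper - lower) / 3.92`, the fit uses
#' `sigma^2 = log(1 + sd^2 / mean^2)` and
#' `mu = log(mean) - sigma^2 / 2`, so the fitted arithmetic mean equals
#' the input mean. A zero-width interval degenerates to a point mass at
#' the mean (`sigma = 0`).
#'
#' @param mean Arithmetic mean, strictly positive.
#' @param lower,upper Interval bounds with `0 < lower <= mean <= upper`.
#' @return Named numeric vector `c(mu = ..., sigma = ...)` on the log
#'   scale.
#' @export
fit_lognormal_from_interval <- function(mean, lower, upper) {
  if (!is.finite(mean) || mean <= 0) {
    stop("lognormal fit requires a positive mean", call. = FALSE)
  }
  stopifnot(lower <= mean, mean <= upper)
  sd <- (upper - lower) / 3.92
  sigma2 <- log(1 + sd^2 / mean^2)
  c(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

# Draw one value for an uncertainty-table row, using the current RNG
# stream. Bounds are normalized before fitting.
draw_uncertain <- function(row) {
  b <- normalize_interval(row$mean, row$lower, row$upper, row$clerical)
  if (row$family != "fixed" && b[1] == b[2]) return(row$mean)
  switch(row$family,
    fixed = row$mean,
    beta = {
      sh <- fit_beta_from_interval(row$mean, b[1], b[2])
      stats::rbeta(1, sh["alpha"], sh["beta"])
    },
    lognormal = {
      ls <- fit_lognormal_from_interval(row$mean, b[1], b[2])
      stats::rlnorm(1, ls["mu"], ls["sigma"])
    },
    uniform = stats::runif(1, b[1], b[2]),
    stop("unknown distribution family: ", row$family, call. = FALSE)
  )
}
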