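#' Microsimulation validation of the cohort engine
#'
#' Individual-level stochastic walk through the same per-cycle
#' transition matrices used by [run_markov_branch()], with identical
#' accounting (half-cycle trapezoidal or end-of-cycle occupancy,
#' mid-cycle or end-of-cycle discounting, annual long-term cost
#' accrual, undiscounted upfront cost). Serves as an independent
#' Monte-Carlo oracle for the deterministic cohort projection: the
#' cohort per-patient values should lie within a few standard errors of
#' the microsimulation means.
#'
#' @param profile A `branch_profile`.
#' @param count Integer number of simulated patients.
#' @param epi,econ,lifetable As in [run_markov_branch()].
#' @param seed Integer seed for the patient-level random walk.
#' @return A list of class `microsim_estimate` with per-patient
#'   `mean_cost`, `se_cost`, `mean_ly`, `se_ly`, totals scaled to
#'   `count`, and `n`.
#' @export
microsimulate_branch <- function(profile, count, epi, econ, lifetable,
                                 seed = 1L) {
  stopifnot(count == as.integer(count), count > 0)
  n <- as.integer(count)
  set.seed(seed)
  state <- rep.int(match(profile$start_state, .STATES), n)
  annual <- profile$annual_cost_by_state
  cost <- rep.int(profile$upfront_cost, n)
  ly <- numeric(n)
  half <- econ$half_cycle_correction
  for (t in seq_len(econ$horizon_years)) {
    age <- epi$initial_age + t - 1
    P <- build_transition_matrix(profile, age, lifetable)
    cum <- t(apply(P, 1, cumsum))
    u <- stats::runif(n)
    # next state: first column of the cumulative row exceeding u
    new_state <- max.col(cum[state, , drop = FALSE] >= u,
                         ties.method = "first")
    w <- discount_weight(t, econ$discount_rate, half)
    alive0 <- state != 4L
    alive1 <- new_state != 4L
    if (half) {
      ly <- ly + w * (alive0 + alive1) / 2
      cost <- cost + w * (annual[state] + annual[new_state]) / 2
    } else {
      ly <- ly + w * alive1
      cost <- cost + w * annual[new_state]
    }
    state <- new_state
  }
  structure(list(n = n,
                 mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
                 mean_ly = mean(ly), se_ly = stats::sd(ly) / sqrt(n),
                 total_cost = sum(cost), total_ly = sum(ly),
                 seed = seed),
            class = "microsim_estimate")
}
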