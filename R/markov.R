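#' Combine disease-specific and background mortality
#'
#' Independent competing risks: the probability of dying within a cycle
#' from either cause is `1 - (1 - p_disease) * (1 - p_background)`.
#' Commutative, and bounded in \[0, 1\] for inputs in \[0, 1\].
#'
#' @param p_disease Annual disease-specific death probability.
#' @param p_background Annual background (all-cause, disease-unrelated)
#'   death probability.
#' @return Combined annual death probability.
#' @export
combine_mortality <- function(p_disease, p_background) {
  stopifnot(all(p_disease >= 0 & p_disease <= 1),
            all(p_background >= 0 & p_background <= 1))
  1 - (1 - p_disease) * (1 - p_background)
}

#' Present-value weight for one model cycle
#'
#' With half-cycle correction on, events are assumed to occur midway
#' through the cycle, so cycle `t` is discounted by
#' `(1 + rate)^-(t - 0.5)`; otherwise by `(1 + rate)^-t`.
#'
#' @param cycle_index Cycle number, integer `>= 1`.
#' @param rate Annual discount rate (`>= 0`).
#' @param half_cycle Logical; mid-cycle discounting when `TRUE`.
#' @return Discount weight in (0, 1\].
#' @export
discount_weight <- function(cycle_index, rate, half_cycle = TRUE) {
  if (any(cycle_index < 1)) stop("cycle_index must be >= 1", call. = FALSE)
  stopifnot(rate >= 0)
  expo <- if (half_cycle) cycle_index - 0.5 else cycle_index
  (1 + rate)^(-expo)
}

#' Branch profile: costs and hazards for one decision-tree branch
#'
#' Encodes the treatment pathway behind each diagnostic outcome:
#' \itemize{
#'   \item TN — elective nodal dissection up front; disease-free
#'     survival subject to background mortality only.
#'   \item FP — unnecessary radical nodal dissection up front; otherwise
#'     as TN.
#'   \item TP — tumour resection + nodal dissection + adjuvant
#'     chemotherapy up front; while disease-free, the annual N+
#'     disease-specific death probability applies.
#'   \item FN — as TP (the disease is treated once it declares itself)
#'     but with the higher recurrence probability that follows an
#'     incomplete elective dissection.
#'   \item METASTATIC — starts in the metastatic state with no upfront
#'     cost; accrues the annual metastatic-disease (palliative) cost.
#' }
#' All non-metastatic branches start disease-free and accrue the annual
#' follow-up cost while disease-free and the annual recurrence cost
#' while recurrent. Patients in recurrence face the N+ disease-specific
#' death probability; metastatic patients the metastatic one. The
#' `recurrence_mortality` switch offers an alternative reading in which
#' recurrent patients face background mortality only — see the methods
#' vignette for why both readings are plausible.
#'
#' @param branch_kind One of `"TN"`, `"FP"`, `"TP"`, `"FN"`,
#'   `"METASTATIC"`.
#' @param costs The `costs` element of an `nstage_params` object.
#' @param transitions The `transitions` element.
#' @param recurrence_mortality `"nplus"` (default): recurrent patients
#'   face the N+ disease-specific death probability; `"background"`:
#'   background mortality only while recurrent.
#' @return A list of class `branch_profile` with fields `branch_kind`,
#'   `start_state`, `upfront_cost`, `annual_cost_by_state` (named over
#'   the four states; zero for DEAD), `p_recurrence`,
#'   `p_disease_death_disease_free`, `p_disease_death_recurrence`,
#'   `p_disease_death_metastatic`.
#' @export
build_branch_profile <- function(branch_kind, costs, transitions,
                                 recurrence_mortality = c("nplus",
                                                          "background")) {
  recurrence_mortality <- match.arg(recurrence_mortality)
  p_death_rec <- switch(recurrence_mortality,
                        nplus = transitions$p_death_nplus,
                        background = 0)
  annual <- c(DISEASE_FREE = costs$followup_annual,
              RECURRENCE = costs$recurrence_annual,
              METASTATIC = costs$metastatic_annual,
              DEAD = 0)
  base <- list(
    start_state = "DISEASE_FREE",
    annual_cost_by_state = annual,
    p_disease_death_recurrence = p_death_rec,
    p_disease_death_metastatic = transitions$p_death_metastatic
  )
  spec <- switch(branch_kind,
    TN = list(upfront_cost = costs$elective_dissection,
              p_recurrence = transitions$p_recurrence_tn,
              p_disease_death_disease_free = 0),
    FP = list(upfront_cost = costs$radical_dissection,
              p_recurrence = transitions$p_recurrence_fp,
              p_disease_death_disease_free = 0),
    TP = list(upfront_cost = costs$resection_nodal_chemo,
              p_recurrence = transitions$p_recurrence_tp,
              p_disease_death_disease_free = transitions$p_death_nplus),
    FN = list(upfront_cost = costs$resection_nodal_chemo,
              p_recurrence = transitions$p_recurrence_fn,
              p_disease_death_disease_free = transitions$p_death_nplus),
    METASTATIC = list(start_state = "METASTATIC", upfront_cost = 0,
                      p_recurrence = 0,
                      p_disease_death_disease_free = 0),
    stop("unknown branch_kind: ", branch_kind, call. = FALSE)
  )
  profile <- utils::modifyList(base, spec)
  profile$branch_kind <- branch_kind
  structure(profile, class = "branch_profile")
}

#' One-cycle transition matrix for a branch at a given age
#'
#' Rows and columns are ordered DISEASE_FREE, RECURRENCE, METASTATIC,
#' DEAD. Death is resolved jointly with recurrence: the disease-free row
#' sends `combine_mortality(p_disease_death_disease_free, q(age))` to
#' DEAD and `p_recurrence * (1 - that death probability)` to RECURRENCE
#' (recurrence only among cycle survivors, which keeps the row
#' stochastic without double counting); the recurrence and metastatic
#' rows send their combined mortality to DEAD and otherwise stay; the
#' DEAD row is the identity (absorbing state).
#'
#' @param profile A `branch_profile`.
#' @param age Attained age (looked up in the life table).
#' @param lifetable A `lifetable` covering `age`.
#' @return A 4x4 row-stochastic matrix (each row sums to 1 within
#'   1e-12).
#' @export
build_transition_matrix <- function(profile, age, lifetable) {
  q <- lifetable_q(lifetable, age)
  d_df <- combine_mortality(profile$p_disease_death_disease_free, q)
  d_rec <- combine_mortality(profile$p_disease_death_recurrence, q)
  d_met <- combine_mortality(profile$p_disease_death_metastatic, q)
  to_rec <- profile$p_recurrence * (1 - d_df)
  P <- matrix(0, 4, 4, dimnames = list(.STATES, .STATES))
  P["DISEASE_FREE", ] <- c(1 - d_df - to_rec, to_rec, 0, d_df)
  P["RECURRENCE", ] <- c(0, 1 - d_rec, 0, d_rec)
  P["METASTATIC", ] <- c(0, 0, 1 - d_met, d_met)
  P["DEAD", "DEAD"] <- 1
  if (any(abs(rowSums(P) - 1) > 1e-12) || any(P < -1e-15)) {
    stop("internal error: transition matrix not row-stochastic",
         call. = FALSE)
  }
  P
}

#' Project one branch through the Markov model
#'
#' Iterates the cohort occupancy for `horizon_years` annual cycles, with
#' attained age advancing one year per cycle from the initial age.
#' Per-cycle life years are the discounted alive occupancy — the
#' trapezoidal mean of start- and end-of-cycle alive mass under
#' half-cycle correction (the default), or the end-of-cycle mass
#' otherwise. Per-cycle costs are the discounted state-occupancy-weighted
#' annual costs under the same occupancy convention. The upfront
#' treatment cost is charged undiscounted at cycle 0.
#'
#' `longterm_cost` selects how the recurrence and metastatic-disease
#' costs accrue: `"annual"` (default) charges them per person-year in
#' state; `"oneoff"` charges the recurrence cost once on entry into the
#' recurrence state (and, for a branch starting metastatic, the
#' metastatic cost once per patient at time zero), with the disease-free
#' follow-up cost still annual.
#'
#' @param profile A `branch_profile`.
#' @param count Fractional number of patients entering the branch
#'   (`>= 0`).
#' @param epi The `epidemiology` element of an `nstage_params` object
#'   (supplies the initial age).
#' @param econ The `economics` element (discount rate, horizon,
#'   half-cycle flag).
#' @param lifetable A `lifetable` covering the ages traversed.
#' @param longterm_cost `"annual"` or `"oneoff"`.
#' @return A list of class `branch_outcome` with `total_discounted_cost`,
#'   `total_discounted_ly` and `trace`, a per-cycle data frame (cycle,
#'   age, end-of-cycle occupancy per state, discounted life-year and
#'   cost increments).
#' @export
run_markov_branch <- function(profile, count, epi, econ, lifetable,
                              longterm_cost = c("annual", "oneoff")) {
  longterm_cost <- match.arg(longterm_cost)
  stopifnot(count >= 0)
  half <- econ$half_cycle_correction
  T_ <- econ$horizon_years
  occ <- stats::setNames(numeric(4), .STATES)
  occ[profile$start_state] <- count
  cost0 <- count * profile$upfront_cost
  if (longterm_cost == "oneoff" && profile$start_state == "METASTATIC") {
    cost0 <- cost0 + count * profile$annual_cost_by_state[["METASTATIC"]]
  }
  annual <- profile$annual_cost_by_state
  if (longterm_cost == "oneoff") {
    annual[c("RECURRENCE", "METASTATIC")] <- 0
  }
  trace <- vector("list", T_)
  total_cost <- cost0
  total_ly <- 0
  for (t in seq_len(T_)) {
    age <- epi$initial_age + t - 1
    P <- build_transition_matrix(profile, age, lifetable)
    occ_end <- drop(occ %*% P)
    w <- discount_weight(t, econ$discount_rate, half)
    mocc <- if (half) (occ + occ_end) / 2 else occ_end
    ly_inc <- w * sum(mocc[.STATES != "DEAD"])
    cost_inc <- w * sum(mocc * annual)
    if (longterm_cost == "oneoff") {
      entrants <- occ[["DISEASE_FREE"]] * P["DISEASE_FREE", "RECURRENCE"]
      cost_inc <- cost_inc +
        w * entrants * profile$annual_cost_by_state[["RECURRENCE"]]
    }
    total_ly <- total_ly + ly_inc
    total_cost <- total_cost + cost_inc
    trace[[t]] <- data.frame(cycle = t, age = age,
                             t(occ_end), ly_disc = ly_inc,
                             cost_disc = cost_inc)
    occ <- occ_end
  }
  trace <- if (T_ > 0) do.call(rbind, trace) else
    data.frame(cycle = integer(), age = numeric(),
               DISEASE_FREE = numeric(), RECURRENCE = numeric(),
               METASTATIC = numeric(), DEAD = numeric(),
               ly_disc = numeric(), cost_disc = numeric())
  rownames(trace) <- NULL
  structure(list(branch_kind = profile$branch_kind, count = count,
                 total_discounted_cost = unname(total_cost),
                 total_discounted_ly = unname(total_ly),
                 upfront_cost = unname(cost0), trace = trace),
            class = "branch_outcome")
}

#' Evaluate one staging strategy end to end
#'
#' Allocates the cohort with the decision tree, projects all five
#' branches through the Markov model, and sums discounted costs and life
#' years, adding the undiscounted examination cost.
#'
#' @param params An `nstage_params` object.
#' @param strategy Strategy name (`"CT"`, `"MRI"`, `"PETCT"`) or a
#'   `strategy` object.
#' @param lifetable A `lifetable`; defaults to [default_lifetable()].
#' @param recurrence_mortality,longterm_cost Passed to
#'   [build_branch_profile()] and [run_markov_branch()].
#' @return A list of class `strategy_outcome` with the allocation, the
#'   per-branch outcomes, `exam_cost`, `total_cost` (including exam
#'   cost), `total_ly`, and the economics settings used.
#' @export
evaluate_strategy <- function(params, strategy,
                              lifetable = default_lifetable(),
                              recurrence_mortality = "nplus",
                              longterm_cost = "annual") {
  if (is.character(strategy)) strategy <- make_strategy(params, strategy)
  alloc <- allocate_cohort(params$epidemiology, strategy)
  counts <- allocation_counts(alloc)
  branches <- lapply(.BRANCHES, function(b) {
    profile <- build_branch_profile(b, params$costs, params$transitions,
                                    recurrence_mortality)
    run_markov_branch(profile, counts[[b]], params$epidemiology,
                      params$economics, lifetable, longterm_cost)
  })
  names(branches) <- .BRANCHES
  branch_cost <- sum(vapply(branches, `[[`, 0, "total_discounted_cost"))
  branch_ly <- sum(vapply(branches, `[[`, 0, "total_discounted_ly"))
  structure(list(
    strategy = strategy$name,
    allocation = alloc,
    branches = branches,
    exam_cost = alloc$exam_cost_total,
    total_cost = branch_cost + alloc$exam_cost_total,
    total_ly = branch_ly,
    cohort_size = params$epidemiology$cohort_size,
    economics = params$economics
  ), class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("<strategy_outcome> %s\n", x$strategy))
  for (b in .BRANCHES) {
    br <- x$branches[[b]]
    cat(sprintf("  %-11s %8.2f pts  EUR %14.2f  %8.2f LY\n", b, br$count,
                br$total_discounted_cost, br$total_discounted_ly))
  }
  cat(sprintf("  exam cost   EUR %.2f\n", x$exam_cost))
  cat(sprintf("  TOTAL       EUR %.2f, %.2f LY (%g patients)\n",
              x$total_cost, x$total_ly, x$cohort_size))
  invisible(x)
}
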