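test_that("competing-risk mortality combination behaves as stated", {
  expect_equal(combine_mortality(0.17, 0), 0.17)
  expect_equal(combine_mortality(1.0, 0.3), 1.0)
  expect_equal(combine_mortality(0.17, 0.02), 0.1866)
  expect_equal(combine_mortality(0.02, 0.17), combine_mortality(0.17, 0.02))
  expect_error(combine_mortality(1.2, 0))
})

test_that("discount weights use mid-cycle exponents under half-cycle correction", {
  expect_equal(discount_weight(1:10, 0), rep(1, 10))
  expect_equal(discount_weight(1, 0.03, half_cycle = TRUE), 1.03^-0.5)
  expect_equal(discount_weight(4, 0.03, half_cycle = FALSE), 1.03^-4)
  expect_error(discount_weight(0, 0.03), ">= 1")
  # brute-force summation oracle for the 10-cycle present-value factor
  brute <- sum((1.03)^-((1:10) - 0.5))
  expect_equal(sum(discount_weight(1:10, 0.03, TRUE)), brute,
               tolerance = 1e-15)
})

test_that("branch profiles encode the treatment pathways", {
  tn <- build_branch_profile("TN", bp$costs, bp$transitions)
  expect_equal(tn$upfront_cost, 4271)
  expect_equal(tn$p_recurrence, 0.128)
  expect_equal(tn$p_disease_death_disease_free, 0)
  expect_equal(unname(tn$annual_cost_by_state["DISEASE_FREE"]), 400)
  expect_equal(unname(tn$annual_cost_by_state["RECURRENCE"]), 32269)
  expect_equal(unname(tn$annual_cost_by_state["DEAD"]), 0)
  expect_equal(tn$start_state, "DISEASE_FREE")

  fp <- build_branch_profile("FP", bp$costs, bp$transitions)
  expect_equal(fp$upfront_cost, 4271)  # radical dissection tariff
  tp <- build_branch_profile("TP", bp$costs, bp$transitions)
  expect_equal(tp$upfront_cost, 24604)
  expect_equal(tp$p_disease_death_disease_free, 0.17)
  fn <- build_branch_profile("FN", bp$costs, bp$transitions)
  expect_equal(fn$p_recurrence, 0.157)
  met <- build_branch_profile("METASTATIC", bp$costs, bp$transitions)
  expect_equal(met$start_state, "METASTATIC")
  expect_equal(met$upfront_cost, 0)
  expect_equal(unname(met$annual_cost_by_state["METASTATIC"]), 32269)
  expect_equal(met$p_disease_death_metastatic, 0.17)
  expect_error(build_branch_profile("XX", bp$costs, bp$transitions),
               "unknown branch_kind")

  # alternative reading: background mortality only while recurrent
  tn_bg <- build_branch_profile("TN", bp$costs, bp$transitions,
                                recurrence_mortality = "background")
  expect_equal(tn_bg$p_disease_death_recurrence, 0)
  expect_equal(tn$p_disease_death_recurrence, 0.17)
})

test_that("transition matrices compose recurrence and death correctly", {
  zero_trans <- lapply(bp$transitions, function(...) 0)
  prof0 <- build_branch_profile("TN", bp$costs, zero_trans)
  P <- build_transition_matrix(prof0, 63, flat_lifetable(0, 100))
  expect_equal(P, diag(4), ignore_attr = TRUE)

  # certain background death empties every living state
  P <- build_transition_matrix(prof0, 63, flat_lifetable(1, 100))
  expect_equal(unname(P[1:3, "DEAD"]), c(1, 1, 1))

  # hand evaluation of the stated composition rule for the TN profile
  tn <- build_branch_profile("TN", bp$costs, bp$transitions)
  P <- build_transition_matrix(tn, 63, flat_lifetable(0.02, 100))
  expect_equal(unname(P["DISEASE_FREE", "DEAD"]), 0.02)
  expect_equal(unname(P["DISEASE_FREE", "RECURRENCE"]), 0.128 * 0.98)
  expect_equal(rowSums(P), c(DISEASE_FREE = 1, RECURRENCE = 1,
                             METASTATIC = 1, DEAD = 1))
})

test_that("transition matrices are row-stochastic across random scenarios", {
  # 1,000 scenario x branch x age combinations
  for (seed in 1:50) {
    p <- random_scenario(seed)
    ages <- seq(p$epidemiology$initial_age, length.out = 4)
    for (b in c("TN", "FP", "TP", "FN", "METASTATIC")) {
      prof <- build_branch_profile(b, p$costs, p$transitions)
      for (age in ages) {
        P <- build_transition_matrix(prof, floor(age), lt)
        expect_true(all(abs(rowSums(P) - 1) < 1e-12))
        expect_true(all(P >= 0 & P <= 1))
        expect_equal(unname(P["DEAD", ]), c(0, 0, 0, 1))
      }
    }
  }
})

test_that("degenerate branches produce the expected outcomes", {
  tp <- build_branch_profile("TP", bp$costs, bp$transitions)
  out0 <- run_markov_branch(tp, 0, bp$epidemiology, bp$economics, lt)
  expect_equal(out0$total_discounted_cost, 0)
  expect_equal(out0$total_discounted_ly, 0)

  econ0 <- bp$economics
  econ0$horizon_years <- 0L
  out <- run_markov_branch(tp, 5, bp$epidemiology, econ0, lt)
  expect_equal(out$total_discounted_cost, 5 * 24604)
  expect_equal(out$total_discounted_ly, 0)
  expect_equal(nrow(out$trace), 0)
})

test_that("constant-hazard life years match the geometric closed form", {
  # per-patient branch with constant total death probability p = 0.17,
  # no discounting, half-cycle trapezoid: LY -> (2 - p) / (2 p)
  p <- 0.17
  trans <- bp$transitions
  trans$p_death_nplus <- p
  trans$p_recurrence_tp <- 0
  prof <- build_branch_profile("TP", bp$costs, trans)
  epi <- bp$epidemiology
  epi$initial_age <- 0
  econ <- bp$economics
  econ$discount_rate <- 0
  econ$horizon_years <- 600L
  out <- run_markov_branch(prof, 1, epi, econ, flat_lifetable(0))
  expect_equal(out$total_discounted_ly, (2 - p) / (2 * p),
               tolerance = 1e-9)
  expect_equal(out$total_discounted_ly, 5.3824, tolerance = 1e-4)

  # truncation at T = 10 matches the finite trapezoidal sum
  econ$horizon_years <- 10L
  out10 <- run_markov_branch(prof, 1, epi, econ, flat_lifetable(0))
  finite <- sum(((1 - p)^(0:9) + (1 - p)^(1:10)) / 2)
  expect_equal(out10$total_discounted_ly, finite, tolerance = 1e-12)
})

test_that("occupancy is conserved and death is absorbing along every trace", {
  for (seed in c(3, 11, 27)) {
    p <- random_scenario(seed)
    for (b in c("TN", "FP", "TP", "FN", "METASTATIC")) {
      prof <- build_branch_profile(b, p$costs, p$transitions)
      out <- run_markov_branch(prof, 7.5, p$epidemiology, p$economics, lt)
      occ <- as.matrix(out$trace[, c("DISEASE_FREE", "RECURRENCE",
                                     "METASTATIC", "DEAD")])
      expect_true(all(abs(rowSums(occ) - 7.5) < 1e-9))
      expect_true(all(occ >= -1e-12))
      expect_true(all(diff(occ[, "DEAD"]) >= -1e-12))
      expect_equal(out$total_discounted_cost,
                   out$upfront_cost + sum(out$trace$cost_disc))
      expect_equal(out$total_discounted_ly, sum(out$trace$ly_disc))
      expect_lte(out$total_discounted_ly,
                 7.5 * p$economics$horizon_years + 1e-9)
    }
  }
})

test_that("discounting shrinks totals and vanishes at rate zero", {
  tn <- build_branch_profile("TN", bp$costs, bp$transitions)
  econ0 <- bp$economics
  econ0$discount_rate <- 0
  disc <- run_markov_branch(tn, 10, bp$epidemiology, bp$economics, lt)
  undisc <- run_markov_branch(tn, 10, bp$epidemiology, econ0, lt)
  expect_lt(disc$total_discounted_ly, undisc$total_discounted_ly)
  expect_lt(disc$total_discounted_cost, undisc$total_discounted_cost)
  # rate 0 reproduces the raw trapezoidal occupancy sums
  occ <- as.matrix(undisc$trace[, c("DISEASE_FREE", "RECURRENCE",
                                    "METASTATIC")])
  alive_end <- rowSums(occ)
  alive_start <- c(10, alive_end[-length(alive_end)])
  expect_equal(undisc$total_discounted_ly,
               sum((alive_start + alive_end) / 2), tolerance = 1e-12)
})

test_that("raising recurrence risk raises cost and weakly lowers life years", {
  for (b in c("TN", "TP")) {
    id <- paste0("p_recurrence_", tolower(substr(b, 1, 2)))
    lo <- build_branch_profile(b, bp$costs, bp$transitions)
    hi_trans <- bp$transitions
    hi_trans[[id]] <- bp$transitions[[id]] + 0.1
    hi <- build_branch_profile(b, bp$costs, hi_trans)
    out_lo <- run_markov_branch(lo, 10, bp$epidemiology, bp$economics, lt)
    out_hi <- run_markov_branch(hi, 10, bp$epidemiology, bp$economics, lt)
    expect_gt(out_hi$total_discounted_cost, out_lo$total_discounted_cost)
    expect_lte(out_hi$total_discounted_ly,
               out_lo$total_discounted_ly + 1e-9)
  }
})

test_that("strategy evaluation separates costs from effects and scales linearly", {
  p0 <- bp
  p0$costs <- lapply(p0$costs, function(x) {
    if (is.list(x)) lapply(x, function(...) 0) else 0
  })
  base <- evaluate_strategy(bp, "PETCT", lt)
  free <- evaluate_strategy(p0, "PETCT", lt)
  expect_equal(free$total_cost, 0)
  expect_equal(free$total_ly, base$total_ly)

  p2 <- bp
  p2$epidemiology$cohort_size <- 200
  double <- evaluate_strategy(p2, "PETCT", lt)
  expect_equal(double$total_cost, 2 * base$total_cost, tolerance = 1e-12)
  expect_equal(double$total_ly, 2 * base$total_ly, tolerance = 1e-12)

  counts <- vapply(base$branches, `[[`, 0, "count")
  expect_equal(unname(counts), c(50.88, 9.12, 24.99, 5.01, 10),
               tolerance = 1e-9)
  expect_equal(base$total_cost - base$exam_cost,
               sum(vapply(base$branches, `[[`, 0, "total_discounted_cost")))
})

test_that("long-term cost accrual toggle switches annual to on-entry charging", {
  met <- build_branch_profile("METASTATIC", bp$costs, bp$transitions)
  annual <- run_markov_branch(met, 10, bp$epidemiology, bp$economics, lt)
  oneoff <- run_markov_branch(met, 10, bp$epidemiology, bp$economics, lt,
                              longterm_cost = "oneoff")
  # one-off: the metastatic cost is charged once per patient at entry
  expect_equal(oneoff$total_discounted_cost, 10 * 32269)
  # annual accrual charges per person-year in state, which is larger
  # over a multi-year horizon with ~3.9 discounted years in state
  expect_gt(annual$total_discounted_cost, oneoff$total_discounted_cost)
})
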