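# Shared fixtures, built in code once per test run.
bp <- baseline_parameters()
lt <- default_lifetable()

# Minimal strategy_outcome stand-in for exercising the incremental
# comparison logic on synthetic cost/effect pairs.
fake_outcome <- function(name, cost, ly, n = 100) {
  structure(list(strategy = name, total_cost = cost, total_ly = ly,
                 cohort_size = n,
                 economics = list(discount_rate = 0.03, horizon_years = 10L,
                                  cycle_length_years = 1,
                                  half_cycle_correction = TRUE)),
            class = "strategy_outcome")
}

# A flat life table (constant annual background mortality), handy for
# closed-form checks.
flat_lifetable <- function(q, age_max = 2000L) {
  make_lifetable(0:age_max, rep(q, age_max + 1))
}
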