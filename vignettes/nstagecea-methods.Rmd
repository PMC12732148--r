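---
title: "Model and methods: cost-effectiveness of imaging for cervical nodal staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: cost-effectiveness of imaging for cervical nodal staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nstagecea)
```

## The decision problem

A patient with head and neck cancer and a clinically N0 neck (no palpable
nodal disease) must be staged before treatment. The choice of imaging —
whole-body CT, neck MRI plus chest/abdominal CT ("MRI"), or whole-body
FDG-PET/CT — changes who is operated on and how: a false-positive scan sends
an N0 patient to an unnecessary radical neck dissection, a false-negative
leaves N+ disease under-treated by an elective dissection and raises the
recurrence risk. This package implements a decision-analytic model that
prices those misclassifications over a 10-year horizon in a national-payer
setting (EOPYY tariffs, EUR 2024) and compares the three strategies by
incremental cost-effectiveness ratio (ICER, EUR per life year gained) and
dominance.

The model has two stages:

1. **Decision tree** (`allocate_cohort()`). A cohort of `N = 100` patients
   aged 63 is split by pre-test prevalence and test accuracy. Nodal
   prevalence `p = 0.30` and metastatic prevalence `m = 0.10` are both
   fractions of the full cohort; metastatic (non-resectable) patients
   bypass the accuracy split, so their branch is identical under every
   strategy. The remaining `N(1 - p - m)` N0 patients split by specificity
   into true negatives and false positives; the `Np` N+ patients split by
   sensitivity into true positives and false negatives. Counts are
   fractional — the cohort is continuous and nothing is rounded.
2. **Markov cohort model** (`run_markov_branch()`). Each branch is
   projected through four health states — disease-free, recurrence,
   metastatic, dead — in annual cycles, with dead absorbing and attained
   age advancing one year per cycle.

## Transition structure

Per cycle and branch the transition matrix is built by
`build_transition_matrix()` from three hazards:

* **Background mortality** `q(age)`, looked up in a life table by attained
  age.
* **Disease-specific mortality**: N+ patients (TP and FN branches) face an
  annual disease death probability of 0.17 from the first cycle onward
  while disease-free; N0 patients (TN, FP) face background mortality only
  until recurrence. Patients in the recurrence state face the same 0.17 N+
  hazard, metastatic patients their own 0.17 hazard.
* **Recurrence**: annual probability 0.128 after a correct N0 diagnosis
  (TN), after an unnecessary radical dissection (FP), and after an
  appropriate radical dissection (TP); 0.157 after the incomplete elective
  dissection received by false negatives.

Disease and background mortality combine as independent competing risks,
`1 - (1 - p_disease)(1 - q)`, and recurrence happens only among cycle
survivors (`p_recurrence × (1 - death)`), which keeps every row stochastic
without double counting. There is no recurrence-to-metastatic transition:
the published parameterization provides no such probability, so the state
space is the only structure the inputs can support.

### An open structural question: mortality while recurrent

The parameter table labels the 17% death probability as applying to N+
patients "initially and after recurrence". Read literally (the default
here, `recurrence_mortality = "nplus"`), every recurrent patient — N0 or
N+ in origin — dies at 17%/year plus background. The published per-branch
results, however, are hard to reconcile with that reading: the
true-negative branch reports about 8.0 discounted life years per patient,
which is only attainable if recurrent N0 patients face background
mortality alone (the literal reading yields about 6.4), while the
true-positive branch's ~3.4 life years per patient *requires* the 17%
hazard from cycle 1. No single structure reproduces all published branch
values (see "Fidelity" below). Both readings therefore ship:
`recurrence_mortality = "background"` applies background-only mortality in
the recurrence state. The default stays with the literal reading of the
parameter table.

## Accounting

* **Cycle length** is one year; the **horizon** is 10 cycles.
* **Discounting** at 3%/year. With **half-cycle correction** (the default)
  events are assumed to occur mid-cycle: per-cycle life years are the
  trapezoidal mean of start- and end-of-cycle alive mass, costs use the
  same trapezoidal state occupancy, and the discount exponent is
  `t - 0.5`. The alternative (`half_cycle_correction = FALSE`, CLI
  `--half-cycle end`) counts end-of-cycle occupancy discounted at
  `(1+r)^-t`. The published life-year figures for the high-mortality
  branches sit closer to end-of-cycle counting (TP ≈ 3.46 vs 3.91
  trapezoidal per patient with the default life table) despite the stated
  correction; trapezoidal remains the default because it is what the
  stated method implies.
* **Upfront treatment costs** (elective dissection EUR 4,271; radical
  dissection EUR 4,271; tumour resection + nodal dissection + adjuvant
  chemotherapy EUR 24,604) and **exam costs** (EUR 383/592/580 per
  patient) are charged once, undiscounted, at time zero.
* **Long-term costs** accrue annually per person-year in state: EUR
  400/year disease-free follow-up (all branches), EUR 32,269/year in
  recurrence and in metastatic disease (treatment plus palliative-care
  add-on). Annual accrual is the default because the published
  non-resectable branch total (≈ EUR 1.10M for 10 patients with 34
  discounted life years) equals discounted person-years × 32,269 almost
  exactly; a once-on-entry reading (`longterm_cost = "oneoff"`) ships as
  a toggle and yields ≈ EUR 0.32M for that branch.

## Background mortality: the synthetic life table

The original analysis used national (EHLEIS-style) survival tables that
are not redistributable. `default_lifetable()` substitutes a Gompertz law
`q(x) = 1 - exp(-(a/b) e^{bx}(e^b - 1))` with slope `b = 0.09`/year and
baseline hazard `a` calibrated once (`calibrate_gompertz()`) so that
remaining life expectancy at age 63 is 20 years — a Greek-like value. This
is a documented stand-in, not the original table; any two-column CSV
(`age,qx`) can be supplied instead (`read_lifetable()`, CLI
`--lifetable`). Background mortality at these ages (q ≈ 0.012–0.03 over
63–73) is an order of magnitude below the disease hazards, so results are
not very sensitive to the substitution; it is nevertheless one reason
exact reproduction of the published totals is not expected.

## Parameter uncertainty

Every uncertain parameter carries a published mean and interval and a
distribution family. Intervals are treated as 95% intervals, so the
implied standard deviation is `(upper - lower)/3.92` — the conventional
choice when coverage is unstated.

Several printed intervals are internally inconsistent (bounds inverted,
the mean repeated as a bound, bounds copied from an adjacent row).
`normalize_interval()` keeps consistent intervals verbatim and repairs
inconsistent ones as `[min, max]` of the printed bounds together with a
±10% envelope around the mean — the half-width pattern of the uncorrupted
rows. The follow-up cost row (mean 400 with printed bounds 29,042–35,496,
plainly copied from the adjacent row) is flagged clerical and uses the
±10% envelope alone. The packaged fixture stores the printed values
verbatim with comments marking each corrupted row; repairs happen at
fitting time only.

Fitting: beta by method of moments (`fit_beta_from_interval()`, exact in
the mean, infeasible-variance inputs rejected); lognormal moment-matched
on the natural scale (`fit_lognormal_from_interval()`,
`sigma² = ln(1 + sd²/mean²)`, `mu = ln(mean) - sigma²/2`); the discount
rate samples uniformly on its printed 2–4% bounds. Parameters without a
printed distribution (cohort size, age, horizon) stay fixed.

**One-way DSA** (`one_way_dsa()`) re-evaluates the pairwise comparison at
each parameter's bounds with everything else at base. Entries are ranked
by the spread of incremental net monetary benefit at a reference
willingness-to-pay (default EUR 27,117 per life year, a published
supply-side estimate of the Greek threshold) because raw ICERs flip sign
across dominance regions and cannot be ordered; raw-ICER ranking is
available via `metric = "icer"`.

**PSA** (`run_psa()`) draws all uncertain parameters independently (no
correlation structure is published; sensitivity and specificity of the
same modality are drawn independently), evaluates all three strategies
per draw, and reports dominance probabilities
(`P(ΔC < 0, ΔE > 0)`), the quadrant decomposition of the incremental
cloud, and cost-effectiveness acceptability curves
(`CEAC(λ) = P(λΔE - ΔC > 0)`). The draw count defaults to 1,000
(conventional desk scale; the original iteration count is unpublished)
and the seed is recorded in every output.

## Numerical choices and degenerate inputs

* ΔE with `|ΔE| < 1e-12` is treated as exactly zero and reported as
  equal-effect cost-minimization rather than an infinite ICER.
* Transition rows are validated to sum to 1 within 1e-12 at construction.
* Zero-width uncertainty intervals sample as point masses; the beta
  fitter refuses them (and means at 0 or 1) with a pointer to
  `family = "fixed"`.
* A zero horizon returns the upfront cost and zero life years; an empty
  branch returns zeros.
* A microsimulation twin of the cohort engine
  (`microsimulate_branch()`) replays the same transition matrices at
  patient level with identical accounting and serves as an independent
  Monte-Carlo oracle in the test suite (cohort values must sit within
  three standard errors at 10⁵ patients).

## Fidelity to the published analysis, and what the tests show

The decision-tree layer reproduces the published branch counts and exam
costs exactly (e.g. PET/CT: 50.88 TN / 9.12 FP / 24.99 TP / 5.01 FN / 10
metastatic; exam EUR 58,000). The Markov layer does not reproduce the
published cost totals: with the default toggles and life table this model
yields ≈ EUR 78,300 per patient and 5.61 discounted life years versus the
published ≈ EUR 128,700 and 6.17. The life-year gap (-9%) traces to the
half-cycle/mortality ambiguities above; the cost gap (-39%) cannot be
closed by any documented toggle combination, and the published per-branch
costs are mutually inconsistent with their own per-branch life years
under every structure we tried (the TN branch would need more than half
of its alive person-time in recurrence at a 12.8%/year inflow). The
toggles were reviewed, not refit: defaults follow the stated methods, and
the divergence is reported as found.

Two consequences of the faithful structure are worth flagging. Because
the recurrence and death hazards of the TP and FN branches differ only in
the recurrence probability — and death while recurrent equals death while
disease-free for N+ patients — the two branches have identical expected
survival, and all three strategies therefore produce *exactly* equal
base-case life years. PET/CT is then cheaper at equal effect
(cost-minimizing) rather than strictly dominant over MRI, and no finite
base-case ICER against CT exists. Under parameter uncertainty the tie
breaks draw by draw: the PSA dominance probabilities are well-defined and
land near the published ones (≈ 52% vs MRI, ≈ 48% vs CT at 1,000 draws,
seed 1). The tornado analysis likewise matches the published finding that
recurrence rates after a correct N0 diagnosis drive the results.

What the synthetic inputs do and do not show: the generator emulates the
published parameter table and a Gompertz approximation of national
background mortality. Passing tests demonstrate internal correctness of
the tree/Markov/CEA machinery and tolerance-band agreement with the
published sensitivity analyses; they do not validate the clinical
parameters themselves, nor transfer to settings with different tariffs,
prevalences or mortality.

## Known limitations

* Life years only — no utility weights or QALYs (none are published for
  this population in this setting).
* No recurrence-to-metastatic pathway, no tunnel states, no
  time-in-state-dependent hazards beyond age, no patient-level
  heterogeneity beyond the five branches.
* Costs are EUR 2024 payer tariffs; no inflation adjustment or currency
  conversion.
* Problem sizes used by the checks: 1,000 PSA draws, 10⁵ microsimulated
  patients per branch, 1,000 random property-test scenarios.

## A worked example

```{r, eval = FALSE}
params <- baseline_parameters()
lifetable <- default_lifetable()
outcomes <- lapply(c(PETCT = "PETCT", CT = "CT", MRI = "MRI"),
                   function(s) evaluate_strategy(params, s, lifetable))
comparison_table(outcomes)

tornado <- one_way_dsa(params, lifetable, "PETCT", "CT")
head(tornado[, c("parameter_id", "spread")])

psa <- run_psa(params, lifetable, n_draws = 1000, seed = 1)
psa$p_dominant
```
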