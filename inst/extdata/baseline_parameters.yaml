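# Baseline parameter set: cost-effectiveness of PET/CT vs CT vs MRI for
# initial cervical lymph-node (N-) staging of head-neck cancer.
# All monetary values EUR 2024 (EOPYY tariffs / DRG A01M).
#
# The uncertainty section reproduces the published means and interval
# bounds verbatim, including rows whose printed bounds are internally
# inconsistent (lower > upper, bound == mean, or bounds copied from an
# adjacent row). Those are NOT silently corrected here; the loader
# normalizes every interval to [min, max] of {printed lower, printed
# upper, mean +/- 10%} at fitting time, and rows flagged `clerical: true`
# (bounds plainly copied from another row) fall back to mean +/- 10%.
epidemiology:
  cohort_size: 100          # clinically N0 head-neck cancer patients
  initial_age: 63           # years
  prevalence_nodal: 0.30    # pre-test probability of lymph-node disease
  prevalence_metastatic: 0.10
accuracy:
  CT:
    sensitivity: 0.676
    specificity: 0.670
  MRI:
    sensitivity: 0.706
    specificity: 0.626
  PETCT:
    sensitivity: 0.833
    specificity: 0.848
costs:
  exam:
    CT: 383.0               # neck + chest + upper-lower abdomen CT
    MRI: 592.0              # neck MRI + chest CT + upper-lower abdominal CT
    PETCT: 580.0            # whole-body FDG-PET/CT incl. radiotracer
  elective_dissection: 4271.0
  radical_dissection: 4271.0
  resection_nodal_chemo: 24604.0
  followup_annual: 400.0    # 10 physician visits x EUR 40 per patient-year
  recurrence_annual: 32269.0   # incl. palliative-care add-on
  metastatic_annual: 32269.0   # incl. palliative-care add-on
transitions:
  p_recurrence_tn: 0.128    # after correct diagnosis of N0 neck
  p_recurrence_fp: 0.128    # after unnecessary radical dissection, N0
  p_recurrence_tp: 0.128    # after appropriate radical dissection, N+
  p_recurrence_fn: 0.157    # after incomplete elective dissection, N+
  p_death_nplus: 0.17       # annual, N+ patients (initially and after recurrence)
  p_death_metastatic: 0.17  # annual, metastatic disease
economics:
  discount_rate: 0.03
  horizon_years: 10
  cycle_length_years: 1
  half_cycle_correction: true
uncertainty:
  - {parameter_id: prevalence_nodal, family: beta, mean: 0.30, lower: 0.30, upper: 0.27}
  # ^ printed bounds inverted/equal to mean; normalized to [0.27, 0.33]
  - {parameter_id: prevalence_metastatic, family: beta, mean: 0.10, lower: 0.10, upper: 0.09}
  - {parameter_id: discount_rate, family: uniform, mean: 0.03, lower: 0.02, upper: 0.04}
  - {parameter_id: sensitivity_CT, family: beta, mean: 0.676, lower: 0.608, upper: 0.744}
  - {parameter_id: specificity_CT, family: beta, mean: 0.670, lower: 0.574, upper: 0.767}
  - {parameter_id: sensitivity_MRI, family: beta, mean: 0.706, lower: 0.635, upper: 0.777}
  - {parameter_id: specificity_MRI, family: beta, mean: 0.626, lower: 0.527, upper: 0.726}
  - {parameter_id: sensitivity_PETCT, family: beta, mean: 0.833, lower: 0.750, upper: 0.916}
  - {parameter_id: specificity_PETCT, family: beta, mean: 0.848, lower: 0.763, upper: 0.933}
  - {parameter_id: exam_CT, family: lognormal, mean: 383.0, lower: 344.0, upper: 421.0}
  - {parameter_id: exam_MRI, family: lognormal, mean: 592.0, lower: 532.0, upper: 651.0}
  - {parameter_id: exam_PETCT, family: lognormal, mean: 580.0, lower: 522.0, upper: 638.0}
  - {parameter_id: elective_dissection, family: lognormal, mean: 4271.0, lower: 3844.0, upper: 4698.0}
  - {parameter_id: radical_dissection, family: lognormal, mean: 4271.0, lower: 3844.0, upper: 4698.0}
  - {parameter_id: resection_nodal_chemo, family: lognormal, mean: 24604.0, lower: 22144.0, upper: 27064.0}
  - {parameter_id: followup_annual, family: lognormal, mean: 400.0, lower: 29042.0, upper: 35496.0, clerical: true}
  # ^ printed bounds copied from the adjacent long-term cost row; clerical
  #   flag makes the fit use mean +/- 10% (360-440)
  - {parameter_id: metastatic_annual, family: lognormal, mean: 32269.0, lower: 29042.0, upper: 35496.0}
  - {parameter_id: recurrence_annual, family: lognormal, mean: 32269.0, lower: 29042.0, upper: 35496.0}
  - {parameter_id: p_recurrence_tn, family: beta, mean: 0.128, lower: 0.128, upper: 0.115}
  # ^ this and the next three rows repeat the mean as "lower"; normalized
  #   to [printed minimum, mean + 10%]
  - {parameter_id: p_recurrence_fp, family: beta, mean: 0.128, lower: 0.128, upper: 0.115}
  - {parameter_id: p_recurrence_tp, family: beta, mean: 0.128, lower: 0.128, upper: 0.115}
  - {parameter_id: p_recurrence_fn, family: beta, mean: 0.157, lower: 0.157, upper: 0.141}
  - {parameter_id: p_death_nplus, family: beta, mean: 0.17, lower: 0.17, upper: 0.153}
  - {parameter_id: p_death_metastatic, family: beta, mean: 0.17, lower: 0.128, upper: 0.115}
  # ^ printed bounds copied from the recurrence rows and both below the
  #   mean; the general rule yields [0.115, 0.187]
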