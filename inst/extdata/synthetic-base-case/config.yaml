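schema_version: 1
time_horizon_years: 50
cycle_length_years: 1.0
discount_rate_costs: 0.03
discount_rate_benefits: 0.03
male_fraction: 0.62
start_age_years: 41.0
first_line_distribution:
  imatinib: 0.75
  nilotinib: 0.13
  dasatinib: 0.12
dmr_maintain_prob:
  imatinib: 0.57
  nilotinib: 0.77
  dasatinib: 0.72
apbc_treatment_mix:
  imatinib: 0.5
  dasatinib: 0.5
line_sequencing:
  imatinib:
    nilotinib: 0.5
    dasatinib: 0.5
  nilotinib:
    dasatinib: 1.0
  dasatinib:
    BSC: 1.0
utilities_monitored:
  CML-CP: 0.854
  DMR: 0.94
  TFR: 1.0
  AP/BC: 0.595
utilities_unmonitored:
  CML-CP: 0.854
  AP/BC: 0.595
monitoring_frequency:
  CML-CP: 2.87
  DMR: 2.5
  TFR_year1: 9.0
  TFR_later: 2.0
resource_use:
  CML-CP:
    nurse_led_visit: 1.52
    haematologist_led_visit: 6.88
    xray: 0.0
    ct_scan: 0.0
    full_blood_count: 7.88
    cytogenetic_analysis: 2.96
    bone_marrow_aspiration: 1.2
    fish_test: 2.24
    blood_film_exam: 4.36
    blood_chemistry: 7.52
    blood_transfusion: 0.04
    platelet_transfusion: 0.0
    cytochemistry_analysis: 0.2
  DMR:
    nurse_led_visit: 1.16
    haematologist_led_visit: 3.72
    xray: 0.0
    ct_scan: 0.0
    full_blood_count: 4.52
    cytogenetic_analysis: 2.32
    bone_marrow_aspiration: 0.12
    fish_test: 0.88
    blood_film_exam: 2.0
    blood_chemistry: 4.52
    blood_transfusion: 0.04
    platelet_transfusion: 0.0
    cytochemistry_analysis: 0.0
  TFR:
    nurse_led_visit: 1.16
    haematologist_led_visit: 3.72
    xray: 0.0
    ct_scan: 0.0
    full_blood_count: 4.52
    cytogenetic_analysis: 2.32
    bone_marrow_aspiration: 0.12
    fish_test: 0.88
    blood_film_exam: 2.0
    blood_chemistry: 4.52
    blood_transfusion: 0.04
    platelet_transfusion: 0.0
    cytochemistry_analysis: 0.0
  AP/BC:
    nurse_led_visit: 2.04
    haematologist_led_visit: 14.52
    xray: 3.96
    ct_scan: 0.96
    full_blood_count: 17.52
    cytogenetic_analysis: 3.6
    bone_marrow_aspiration: 3.6
    fish_test: 0.52
    blood_film_exam: 8.76
    blood_chemistry: 12.6
    blood_transfusion: 7.92
    platelet_transfusion: 1.2
    cytochemistry_analysis: 0.48
unit_costs:
  nurse_led_visit: 30.0
  haematologist_led_visit: 40.0
  xray: 70.0
  ct_scan: 170.0
  full_blood_count: 20.0
  cytogenetic_analysis: 490.0
  bone_marrow_aspiration: 100.0
  fish_test: 800.0
  blood_film_exam: 100.0
  blood_chemistry: 350.0
  blood_transfusion: 450.0
  platelet_transfusion: 1420.0
  cytochemistry_analysis: 100.0
drug_costs:
  imatinib: 586.0
  nilotinib: 11364.0
  dasatinib: 7500.0
  interferon: 912.88
ifn_admin_cost: 1095.75
drug_cost_period_multiplier: 12.0
hospital_days_apbc: 36.0
hospital_day_cost: 300.0
monitoring_test_cost: 250.0
terminal_care_cost: 8000.0
terminal_care_trigger: all_deaths
dmr_achievement_multiplier: 1.0
curve_refs:
  TTD:imatinib: curve_TTD_imatinib.csv
  TTD:nilotinib: curve_TTD_nilotinib.csv
  TTD:dasatinib: curve_TTD_dasatinib.csv
  PFS:imatinib: curve_PFS_imatinib.csv
  PFS:nilotinib: curve_PFS_nilotinib.csv
  PFS:dasatinib: curve_PFS_dasatinib.csv
  PFS:BSC: curve_PFS_BSC.csv
  MR4.5:imatinib: curve_MR4_5_imatinib.csv
  MR4.5:nilotinib: curve_MR4_5_nilotinib.csv
  MR4.5:dasatinib: curve_MR4_5_dasatinib.csv
  TFR:all: curve_TFR_all.csv
  OS:AP/BC: curve_OS_AP_BC.csv
provenance:
  male_fraction: base-case clinical inputs table
  start_age_years: base-case clinical inputs table
  discount_rate_costs: base-case clinical inputs table
  discount_rate_benefits: base-case clinical inputs table
  first_line_distribution: base-case clinical inputs table
  dmr_maintain_prob: base-case clinical inputs table
  apbc_treatment_mix: base-case clinical inputs table
  line_sequencing: base-case clinical inputs table
  utilities_monitored: base-case clinical inputs table
  utilities_unmonitored: base-case clinical inputs table
  monitoring_frequency: base-case clinical inputs table
  resource_use: base-case clinical inputs table
  unit_costs: base-case cost inputs table
  drug_costs: base-case cost inputs table
  ifn_admin_cost: base-case cost inputs table
  drug_cost_period_multiplier: assumption
  hospital_days_apbc: base-case clinical inputs table
  hospital_day_cost: base-case cost inputs table
  monitoring_test_cost: base-case cost inputs table
  terminal_care_cost: assumption
  terminal_care_trigger: assumption
  curves: synthetic
  life_table: synthetic
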