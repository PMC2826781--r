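{
  "description": "Base-case configuration: two-arm adjuvant chemotherapy trial summary (5-year outcomes), 2006 CAD unit costs, utility weights and economic settings.",
  "arms": {
    "TAC": {
      "arm_label": "TAC",
      "n_treated": 744,
      "n_recurrences": 141,
      "n_deaths": 162,
      "ae_rates": {
        "febrile_neutropenia": 0.247,
        "stomatitis": 0.071,
        "diarrhea": 0.038,
        "infection": 0.039
      },
      "prophylaxis_patients": 217,
      "prophylaxis_cycles": 799
    },
    "FAC": {
      "arm_label": "FAC",
      "n_treated": 736,
      "n_recurrences": 195,
      "n_deaths": 246,
      "ae_rates": {
        "febrile_neutropenia": 0.025,
        "stomatitis": 0.02,
        "diarrhea": 0.018,
        "infection": 0.022
      },
      "prophylaxis_patients": 41,
      "prophylaxis_cycles": 126
    }
  },
  "costs": {
    "drug_acquisition": {"TAC": 9024.0, "FAC": 301.92},
    "chemo_administration": {"TAC": 1522.08, "FAC": 913.26},
    "ae_unit_costs": {
      "febrile_neutropenia": 2367.23,
      "stomatitis": 3151.18,
      "diarrhea": 2760.3,
      "infection": 2367.3
    },
    "gcsf_cost_per_event": 1239.77,
    "antibiotic_prophylaxis": 314.1,
    "supportive_care_components": {
      "transfusion": {"TAC": 41.6, "FAC": 13.56},
      "ondansetron": {"TAC": 31.5, "FAC": 31.5},
      "dexamethasone": {"TAC": 6.0, "FAC": 6.0}
    },
    "supportive_care_arm_totals": {"TAC": 79.1, "FAC": 51.06},
    "supportive_care_average": 65.08,
    "diagnostics_at_diagnosis": 643.04,
    "lab_tests": 41.95,
    "followup_no_recurrence": {"years_1_3": 582.82, "after_year_3": 356.93},
    "followup_locoregional_schedule": [1032.76, 1032.76, 764.27, 764.27, 620.65, 620.65],
    "followup_metastatic_annual": 1729.1,
    "met_chemo_line_costs": {
      "TAC": {
        "line1": [10686, 54264],
        "line2": [3300, 10686],
        "line3": [18072, 18072]
      },
      "FAC": {
        "line1": [11700, 47892],
        "line2": [3300, 3300],
        "line3": [11700, 11700]
      }
    },
    "her2_positive_fraction": 0.2,
    "line_utilization": {"line1": 0.8, "line2": 0.5, "line3": 0.25}
  },
  "utilities": {
    "u_no_recurrence": 0.96,
    "u_locoregional": 0.816,
    "u_distant_range": [0.49, 0.65],
    "u_adjuvant_fac": 0.72,
    "disutility_tac": 0.0072,
    "disutility_fac": 0.0035
  },
  "settings": {
    "discount_rate_annual": 0.05,
    "cycle_length": 0.5,
    "trial_horizon_cycles": 10,
    "gcsf_days_per_cycle": 7,
    "patient_weight_kg": 60,
    "treatment_phase_cycles": 6,
    "remaining_life_expectancy": {
      "no_recurrence": 28.0,
      "locoregional": 8.0,
      "distant": 2.0
    }
  },
  "transitions": {
    "percent_met_relapse": 0.8,
    "p_met_relapse": 0.065,
    "death_allocation": {
      "no_recurrence": 0.15,
      "locoregional": 0.1,
      "distant": 0.75
    },
    "relapse_scale": {"TAC": 1.0, "FAC": 1.0}
  },
  "primary_prophylaxis": {
    "ae_rates_pre": {
      "febrile_neutropenia": 0.246,
      "stomatitis": 0.064,
      "diarrhea": 0.07,
      "infection": 0.028
    },
    "ae_rates_post": {
      "febrile_neutropenia": 0.065,
      "stomatitis": 0.026,
      "diarrhea": 0.026,
      "infection": 0.017
    },
    "ae_rates_fac": {
      "febrile_neutropenia": 0.023,
      "stomatitis": 0.027,
      "diarrhea": 0.008,
      "infection": 0.018
    },
    "gcsf_cost_all_cycles": 7438.62
  }
}
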