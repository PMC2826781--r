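[
  {
    "name": "Adverse event rates (GEICAM study)",
    "perturbations": [
      {"path": "arms.TAC.ae_rates", "op": "set",
       "value": {"febrile_neutropenia": 0.246, "stomatitis": 0.064,
                 "diarrhea": 0.07, "infection": 0.028}},
      {"path": "arms.FAC.ae_rates", "op": "set",
       "value": {"febrile_neutropenia": 0.023, "stomatitis": 0.027,
                 "diarrhea": 0.008, "infection": 0.018}}
    ]
  },
  {
    "name": "Adverse event rates increased by 25%",
    "perturbations": [
      {"path": "arms.TAC.ae_rates", "op": "scale", "value": 1.25},
      {"path": "arms.FAC.ae_rates", "op": "scale", "value": 1.25}
    ]
  },
  {
    "name": "Adverse event rates decreased by 25%",
    "perturbations": [
      {"path": "arms.TAC.ae_rates", "op": "scale", "value": 0.75},
      {"path": "arms.FAC.ae_rates", "op": "scale", "value": 0.75}
    ]
  },
  {
    "name": "Adverse event rates in TAC increased by 25%",
    "perturbations": [
      {"path": "arms.TAC.ae_rates", "op": "scale", "value": 1.25}
    ]
  },
  {
    "name": "Adverse event rates in TAC decreased by 25%",
    "perturbations": [
      {"path": "arms.TAC.ae_rates", "op": "scale", "value": 0.75}
    ]
  },
  {
    "name": "Rates of febrile neutropenia increased by 25%",
    "perturbations": [
      {"path": "arms.TAC.ae_rates.febrile_neutropenia", "op": "scale", "value": 1.25},
      {"path": "arms.FAC.ae_rates.febrile_neutropenia", "op": "scale", "value": 1.25}
    ]
  },
  {
    "name": "Rates of febrile neutropenia decreased by 25%",
    "perturbations": [
      {"path": "arms.TAC.ae_rates.febrile_neutropenia", "op": "scale", "value": 0.75},
      {"path": "arms.FAC.ae_rates.febrile_neutropenia", "op": "scale", "value": 0.75}
    ]
  },
  {
    "name": "Increased probability of relapse by 25% in TAC arm",
    "perturbations": [
      {"path": "transitions.relapse_scale.TAC", "op": "scale", "value": 1.25}
    ]
  },
  {
    "name": "Decreased probability of relapse by 25% in TAC arm",
    "perturbations": [
      {"path": "transitions.relapse_scale.TAC", "op": "scale", "value": 0.75}
    ]
  },
  {
    "name": "Follow-up cost: no recurrence +25%, metastatic -25%",
    "perturbations": [
      {"path": "costs.followup_no_recurrence", "op": "scale", "value": 1.25},
      {"path": "costs.followup_metastatic_annual", "op": "scale", "value": 0.75}
    ]
  },
  {
    "name": "Follow-up cost: no recurrence -25%, metastatic +25%",
    "perturbations": [
      {"path": "costs.followup_no_recurrence", "op": "scale", "value": 0.75},
      {"path": "costs.followup_metastatic_annual", "op": "scale", "value": 1.25}
    ]
  },
  {
    "name": "Recurrence at 25%",
    "perturbations": [
      {"path": "transitions.percent_met_relapse", "op": "set", "value": 0.25}
    ]
  },
  {
    "name": "Recurrence at 100%",
    "perturbations": [
      {"path": "transitions.percent_met_relapse", "op": "set", "value": 1.0}
    ]
  },
  {
    "name": "Equate utility value",
    "perturbations": [
      {"path": "utilities.disutility_tac", "op": "set", "value": 0.0035}
    ]
  },
  {
    "name": "Lowest utility value",
    "perturbations": [
      {"path": "utilities.u_distant_range", "op": "set", "value": [0.49, 0.49]}
    ]
  },
  {
    "name": "Highest utility value",
    "perturbations": [
      {"path": "utilities.u_distant_range", "op": "set", "value": [0.65, 0.65]}
    ]
  },
  {
    "name": "Primary prophylaxis (G-CSF)",
    "model": "primary_prophylaxis",
    "perturbations": []
  },
  {
    "name": "Primary prophylaxis: adverse event rates increased by 25%",
    "model": "primary_prophylaxis",
    "perturbations": [
      {"path": "primary_prophylaxis.ae_rates_post", "op": "scale", "value": 1.25},
      {"path": "primary_prophylaxis.ae_rates_fac", "op": "scale", "value": 1.25}
    ]
  },
  {
    "name": "Primary prophylaxis: adverse event rates decreased by 25%",
    "model": "primary_prophylaxis",
    "perturbations": [
      {"path": "primary_prophylaxis.ae_rates_post", "op": "scale", "value": 0.75},
      {"path": "primary_prophylaxis.ae_rates_fac", "op": "scale", "value": 0.75}
    ]
  },
  {
    "name": "Primary prophylaxis: adverse event rates in TAC increased by 25%",
    "model": "primary_prophylaxis",
    "perturbations": [
      {"path": "primary_prophylaxis.ae_rates_post", "op": "scale", "value": 1.25}
    ]
  },
  {
    "name": "Primary prophylaxis: adverse event rates in TAC decreased by 25%",
    "model": "primary_prophylaxis",
    "perturbations": [
      {"path": "primary_prophylaxis.ae_rates_post", "op": "scale", "value": 0.75}
    ]
  },
  {
    "name": "Primary prophylaxis: febrile neutropenia rates increased by 25%",
    "model": "primary_prophylaxis",
    "perturbations": [
      {"path": "primary_prophylaxis.ae_rates_post.febrile_neutropenia", "op": "scale", "value": 1.25},
      {"path": "primary_prophylaxis.ae_rates_fac.febrile_neutropenia", "op": "scale", "value": 1.25}
    ]
  },
  {
    "name": "Primary prophylaxis: febrile neutropenia rates decreased by 25%",
    "model": "primary_prophylaxis",
    "perturbations": [
      {"path": "primary_prophylaxis.ae_rates_post.febrile_neutropenia", "op": "scale", "value": 0.75},
      {"path": "primary_prophylaxis.ae_rates_fac.febrile_neutropenia", "op": "scale", "value": 0.75}
    ]
  },
  {
    "name": "Primary prophylaxis: increased probability of relapse by 25% in TAC arm",
    "model": "primary_prophylaxis",
    "perturbations": [
      {"path": "transitions.relapse_scale.TAC", "op": "scale", "value": 1.25}
    ]
  },
  {
    "name": "Primary prophylaxis: decreased probability of relapse by 25% in TAC arm",
    "model": "primary_prophylaxis",
    "perturbations": [
      {"path": "transitions.relapse_scale.TAC", "op": "scale", "value": 0.75}
    ]
  }
]
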