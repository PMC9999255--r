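{
  "values": {
    "u_no_dr": 0.87,
    "u_non_stdr": 0.79,
    "u_stdr": 0.7,
    "u_blind": 0.55,
    "sens_ai": 0.8047,
    "spec_ai": 0.9796,
    "sens_manual": 1,
    "spec_manual": 1,
    "compliance_referral": 0.504,
    "compliance_multiplier_ai": 1,
    "cost_screening_manual": 10.1,
    "cost_screening_ai": 9.6,
    "cost_blind_first_year": 8920,
    "share_blind_direct_medical": 0.532,
    "share_blind_direct_nonmedical": 0.064,
    "share_blind_indirect": 0.404,
    "discount_rate": 0.035,
    "gdp_per_capita": 22600,
    "exchange_rate_cny_per_usd": 6.9,
    "prev_non_stdr": 0.16,
    "prev_stdr": 0.03,
    "prev_dme": 0.02,
    "p_no_dr_to_non_stdr": 0.06,
    "p_non_stdr_to_stdr": 0.05,
    "p_non_stdr_to_dme": 0.03,
    "p_stdr_to_blind": 0.14,
    "p_dme_to_blind": 0.09,
    "treatment_multiplier": 0.43,
    "or_mort_no_dr": 1.28,
    "or_mort_non_stdr": 1.52,
    "or_mort_stdr": 2.05,
    "or_mort_blind": 2.7,
    "cost_referral_direct_medical": 42,
    "cost_referral_direct_nonmedical": 8,
    "cost_referral_indirect": 0,
    "cost_treat_first_dme_direct_medical": 3900,
    "cost_treat_first_dme_direct_nonmedical": 25,
    "cost_treat_first_dme_indirect": 0,
    "cost_treat_first_pdr_direct_medical": 2000,
    "cost_treat_first_pdr_direct_nonmedical": 25,
    "cost_treat_first_pdr_indirect": 0,
    "cost_treat_followup_direct_medical": 1900,
    "cost_treat_followup_direct_nonmedical": 15,
    "cost_treat_followup_indirect": 0,
    "cost_blind_followup_indirect": 5600
  },
  "ranges": {
    "sens_manual": [0.9, 1],
    "spec_manual": [0.95, 1]
  },
  "mortality": [
    {
      "age": 65,
      "qx": 0.036
    },
    {
      "age": 66,
      "qx": 0.0391938144011423
    },
    {
      "age": 67,
      "qx": 0.0426709746475332
    },
    {
      "age": 68,
      "qx": 0.046456618351424
    },
    {
      "age": 69,
      "qx": 0.0505781132602894
    },
    {
      "age": 70,
      "qx": 0.0550652551078816
    },
    {
      "age": 71,
      "qx": 0.0599504830180519
    },
    {
      "age": 72,
      "qx": 0.0652691140185656
    },
    {
      "age": 73,
      "qx": 0.0710595983602961
    },
    {
      "age": 74,
      "qx": 0.0773637974875879
    },
    {
      "age": 75,
      "qx": 0.0842272866693357
    },
    {
      "age": 76,
      "qx": 0.0916996844786043
    },
    {
      "age": 77,
      "qx": 0.0998350115027147
    },
    {
      "age": 78,
      "qx": 0.108692080877036
    },
    {
      "age": 79,
      "qx": 0.118334923465792
    },
    {
      "age": 80,
      "qx": 0.128833250763657
    },
    {
      "age": 81,
      "qx": 0.140262958864628
    },
    {
      "age": 82,
      "qx": 0.152706677141536
    },
    {
      "age": 83,
      "qx": 0.166254365602792
    },
    {
      "age": 84,
      "qx": 0.181003965244875
    },
    {
      "age": 85,
      "qx": 0.197062106102179
    },
    {
      "age": 86,
      "qx": 0.214544878112973
    },
    {
      "age": 87,
      "qx": 0.233578670374322
    },
    {
      "age": 88,
      "qx": 0.254301084853244
    },
    {
      "age": 89,
      "qx": 0.276861931159644
    },
    {
      "age": 90,
      "qx": 0.301424309572582
    },
    {
      "age": 91,
      "qx": 0.328165790149451
    },
    {
      "age": 92,
      "qx": 0.357279696442273
    },
    {
      "age": 93,
      "qx": 0.388976503101525
    },
    {
      "age": 94,
      "qx": 0.423485357471293
    },
    {
      "age": 95,
      "qx": 0.461055736175869
    },
    {
      "age": 96,
      "qx": 0.501959248673863
    },
    {
      "age": 97,
      "qx": 0.54649160081834
    },
    {
      "age": 98,
      "qx": 0.594974732618256
    },
    {
      "age": 99,
      "qx": 0.647759145655811
    },
    {
      "age": 100,
      "qx": 0.705226436985456
    }
  ],
  "settings": {
    "start_age": 65,
    "n_cycles": 30,
    "half_cycle": false,
    "discount_effects": false,
    "currency": "USD",
    "scale_per": 100000,
    "boundary_favorable": true
  }
}
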