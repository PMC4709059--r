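{
  "format": "btcea-parameters",
  "currency_year": 2013,
  "parameters": [
    {
      "name": "rate_ocs",
      "label": "Annual rate of exacerbations requiring oral corticosteroids, standard therapy",
      "value": 1.35,
      "dist": {
        "family": "lognormal",
        "meanlog": 0.29,
        "sdlog": 0.1
      }
    },
    {
      "name": "rate_ed",
      "label": "Annual rate of exacerbations requiring an emergency department visit, standard therapy",
      "value": 0.07,
      "dist": {
        "family": "lognormal",
        "meanlog": -2.72,
        "sdlog": 0.1
      }
    },
    {
      "name": "rate_hosp",
      "label": "Annual rate of exacerbations requiring hospitalization, standard therapy",
      "value": 0.06,
      "dist": {
        "family": "lognormal",
        "meanlog": -2.79,
        "sdlog": 0.1
      }
    },
    {
      "name": "rr_bt_ocs",
      "label": "Relative rate of OCS exacerbations, bronchial thermoplasty vs standard",
      "value": 0.48,
      "dist": {
        "family": "lognormal",
        "meanlog": -0.73,
        "sdlog": 0.3
      }
    },
    {
      "name": "rr_bt_ed",
      "label": "Relative rate of ED exacerbations, bronchial thermoplasty vs standard",
      "value": 0.19,
      "dist": {
        "family": "lognormal",
        "meanlog": -1.64,
        "sdlog": 0.346410161513775
      }
    },
    {
      "name": "rr_bt_hosp",
      "label": "Relative rate of hospitalizations, bronchial thermoplasty vs standard",
      "value": 0.3,
      "dist": {
        "family": "lognormal",
        "meanlog": -1.21,
        "sdlog": 0.374165738677394
      }
    },
    {
      "name": "rr_omalizumab_ocs",
      "label": "Relative rate of OCS exacerbations, omalizumab vs standard",
      "value": 0.63,
      "dist": {
        "family": "lognormal",
        "meanlog": -0.46,
        "sdlog": 0.1
      }
    },
    {
      "name": "rr_omalizumab_ed",
      "label": "Relative rate of ED exacerbations, omalizumab vs standard",
      "value": 0.4,
      "dist": {
        "family": "lognormal",
        "meanlog": -0.92,
        "sdlog": 0.374165738677394
      }
    },
    {
      "name": "rr_omalizumab_hosp",
      "label": "Relative rate of hospitalizations, omalizumab vs standard",
      "value": 0.49,
      "dist": {
        "family": "lognormal",
        "meanlog": -0.72,
        "sdlog": 0.346410161513775
      }
    },
    {
      "name": "death_risk_hosp",
      "label": "30-day risk of death given an asthma hospitalization",
      "value": 0.02,
      "dist": {
        "family": "beta",
        "shape1": 1.1,
        "shape2": 43.22
      }
    },
    {
      "name": "cost_event_ocs",
      "label": "Unit cost of an OCS-treated exacerbation (2013 US$)",
      "value": 130,
      "dist": {
        "family": "gamma",
        "shape": 100,
        "rate": 0.77
      }
    },
    {
      "name": "cost_event_ed",
      "label": "Unit cost of an ED-treated exacerbation (2013 US$)",
      "value": 594,
      "dist": {
        "family": "gamma",
        "shape": 98.01,
        "rate": 0.17
      }
    },
    {
      "name": "cost_event_hosp",
      "label": "Unit cost of a hospitalized exacerbation (2013 US$)",
      "value": 9900,
      "dist": {
        "family": "gamma",
        "shape": 100.08,
        "rate": 0.01
      }
    },
    {
      "name": "cost_drug_standard",
      "label": "Annual cost of standard therapy (2013 US$/person-year)",
      "value": 2610,
      "dist": {
        "family": "fixed"
      }
    },
    {
      "name": "cost_drug_omalizumab",
      "label": "Annual add-on cost of omalizumab (2013 US$/person-year)",
      "value": 22700,
      "dist": {
        "family": "fixed"
      }
    },
    {
      "name": "cost_bt_upfront",
      "label": "One-time cost of bronchial thermoplasty (2013 US$)",
      "value": 14900,
      "dist": {
        "family": "fixed"
      }
    },
    {
      "name": "utility_free",
      "label": "Utility of the exacerbation-free state, standard therapy",
      "value": 0.67,
      "dist": {
        "family": "beta",
        "shape1": 5.92,
        "shape2": 2.93
      }
    },
    {
      "name": "utility_delta_bt",
      "label": "Exacerbation-free utility difference, bronchial thermoplasty vs standard",
      "value": 0.03,
      "dist": {
        "family": "normal",
        "mean": 0.03,
        "sd": 0.02
      }
    },
    {
      "name": "utility_delta_omalizumab",
      "label": "Exacerbation-free utility difference, omalizumab vs standard",
      "value": 0.04,
      "dist": {
        "family": "normal",
        "mean": 0.04,
        "sd": 0.004
      }
    },
    {
      "name": "utility_ocs",
      "label": "Utility while in the OCS exacerbation state",
      "value": 0.57,
      "dist": {
        "family": "beta",
        "shape1": 0.51,
        "shape2": 0.38
      }
    },
    {
      "name": "utility_ed",
      "label": "Utility while in the ED exacerbation state",
      "value": 0.45,
      "dist": {
        "family": "beta",
        "shape1": 0.36,
        "shape2": 0.45
      }
    },
    {
      "name": "utility_hosp",
      "label": "Utility while in the hospitalization exacerbation state",
      "value": 0.33,
      "dist": {
        "family": "beta",
        "shape1": 0.15,
        "shape2": 0.3
      }
    }
  ]
}
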