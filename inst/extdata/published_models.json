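{
  "model1": {
    "name": "Model 1",
    "n": 31,
    "a": -8.670,
    "b": -0.102,
    "c": 1.985,
    "d": 0.105,
    "predictors": [
      {"variable": "age_years", "label": "Age at baseline", "units": "years"},
      {"variable": "log10_vl_baseline", "label": "Log HIV plasma VL at baseline", "units": "log10 copies/mL"},
      {"variable": "rte_pct_6mo", "label": "% RTE among CD4+ T cells at 6 mo", "units": "percent"}
    ]
  },
  "model2": {
    "name": "Model 2",
    "n": 30,
    "a": -15.182,
    "b": 2.519,
    "c": 0.133,
    "d": -2.179,
    "predictors": [
      {"variable": "log10_vl_baseline", "label": "Log HIV plasma VL at baseline", "units": "log10 copies/mL"},
      {"variable": "cd4_slope_0_6", "label": "CD4+ T cell count slope [0, 6] mo", "units": "cells/uL/month"},
      {"variable": "rte_ratio_0_6mo", "label": "% RTE among CD4+ T cells ratio (0/6 mo)", "units": "ratio"}
    ]
  },
  "model3": {
    "name": "Model 3",
    "n": 33,
    "a": -9.703,
    "b": -0.103,
    "c": 1.897,
    "d": 0.013,
    "predictors": [
      {"variable": "age_years", "label": "Age at baseline", "units": "years"},
      {"variable": "log10_vl_baseline", "label": "Log HIV plasma VL at baseline", "units": "log10 copies/mL"},
      {"variable": "cd4_count_6mo", "label": "CD4+ T cell count at 6 mo", "units": "cells/uL"}
    ]
  },
  "model4": {
    "name": "Model 4",
    "n": 31,
    "a": -10.971,
    "b": -0.160,
    "c": 2.610,
    "d": 0.012,
    "predictors": [
      {"variable": "age_years", "label": "Age at baseline", "units": "years"},
      {"variable": "log10_vl_baseline", "label": "Log HIV plasma VL at baseline", "units": "log10 copies/mL"},
      {"variable": "cd4_count_2mo", "label": "CD4+ T cell count at 2 mo", "units": "cells/uL"}
    ]
  }
}
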