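{
  "n": 150,
  "seed": 1,
  "altitude_m": 1700,
  "hb_altitude_adjusted": true,
  "marginals": {
    "hb": {
      "name": "hb",
      "p": [0.066, 0.191, 0.25, 0.5, 0.75],
      "q": [110, 120, 123, 131.5, 139],
      "log_scale": false,
      "floor_value": 0.001,
      "cap_factor": 5,
      "lower": null,
      "upper": null
    },
    "ferritin": {
      "name": "ferritin",
      "p": [0.25, 0.5, 0.75, 0.98],
      "q": [12, 27.6, 56, 150],
      "log_scale": true,
      "floor_value": 0.001,
      "cap_factor": 5,
      "lower": null,
      "upper": null
    },
    "tfr": {
      "name": "tfr",
      "p": [0.25, 0.5, 0.75, 0.92],
      "q": [2, 3.5, 5, 8.3],
      "log_scale": true,
      "floor_value": 0.001,
      "cap_factor": 5,
      "lower": null,
      "upper": null
    },
    "plasma_iron": {
      "name": "plasma_iron",
      "p": [0.25, 0.5, 0.75],
      "q": [11, 14.7, 20],
      "log_scale": true,
      "floor_value": 0.001,
      "cap_factor": 5,
      "lower": null,
      "upper": null
    },
    "hepcidin": {
      "name": "hepcidin",
      "p": [0.25, 0.5, 0.75],
      "q": [4, 7.2, 11],
      "log_scale": true,
      "floor_value": 0.001,
      "cap_factor": 5,
      "lower": null,
      "upper": null
    },
    "crp": {
      "name": "crp",
      "p": [0.25, 0.5, 0.75, 0.94],
      "q": [0.4, 0.8, 1.9, 5],
      "log_scale": true,
      "floor_value": 0.001,
      "cap_factor": 5,
      "lower": null,
      "upper": null
    },
    "agp": {
      "name": "agp",
      "p": [0.25, 0.5, 0.75, 0.87],
      "q": [0.5, 0.7, 0.8, 1],
      "log_scale": true,
      "floor_value": 0.001,
      "cap_factor": 5,
      "lower": null,
      "upper": null
    },
    "zinc": {
      "name": "zinc",
      "p": [0.25, 0.5, 0.78],
      "q": [8, 9.5, 10.7],
      "log_scale": false,
      "floor_value": 0.001,
      "cap_factor": 5,
      "lower": null,
      "upper": null
    },
    "selenium": {
      "name": "selenium",
      "p": [0.25, 0.5, 0.75],
      "q": [2.6, 3, 3.4],
      "log_scale": false,
      "floor_value": 0.001,
      "cap_factor": 5,
      "lower": 2,
      "upper": 5
    }
  },
  "copula": {
    "variables": ["hb", "ferritin", "tfr", "plasma_iron", "hepcidin", "crp", "agp", "zinc", "selenium"],
    "pairs": [
      {
        "var1": "hb",
        "var2": "tfr",
        "r": -0.19
      },
      {
        "var1": "ferritin",
        "var2": "tfr",
        "r": -0.24
      },
      {
        "var1": "hb",
        "var2": "plasma_iron",
        "r": 0.33
      },
      {
        "var1": "ferritin",
        "var2": "plasma_iron",
        "r": 0.32
      },
      {
        "var1": "ferritin",
        "var2": "hepcidin",
        "r": 0.48
      },
      {
        "var1": "plasma_iron",
        "var2": "crp",
        "r": -0.17
      },
      {
        "var1": "hb",
        "var2": "agp",
        "r": -0.23
      },
      {
        "var1": "plasma_iron",
        "var2": "agp",
        "r": -0.16
      },
      {
        "var1": "crp",
        "var2": "agp",
        "r": 0.34
      },
      {
        "var1": "hb",
        "var2": "zinc",
        "r": 0.23
      }
    ],
    "repaired_latent_corr": null
  },
  "categorical_probs": {
    "education": {
      "illiterate": 0.618,
      "literate": 0.382
    },
    "hfias_category": {
      "food_secure": 0.526526526526527,
      "mild": 0.125125125125125,
      "moderate": 0.23023023023023,
      "severe": 0.118118118118118
    },
    "age_band": {
      "18-25": 0.757,
      "26-35": 0.23,
      "36+": 0.013
    },
    "household_size_band": {
      "1-4": 0.385,
      "5-7": 0.412,
      "8+": 0.203
    },
    "children_band": {
      "1-2": 0.441,
      "3-5": 0.441,
      "6+": 0.118
    }
  },
  "anthropometry": {
    "muac": [24.4, 2.4],
    "bmi": [20.7, 2.3]
  },
  "asset_probs": {
    "radio": 0.35,
    "mobile_phone": 0.45,
    "bed": 0.6,
    "corrugated_roof": 0.5,
    "cattle": 0.55,
    "latrine": 0.4,
    "bicycle": 0.15,
    "electricity": 0.1
  },
  "effects": null
}
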