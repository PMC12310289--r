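{
  "grid": {
    "n_rows": 50,
    "n_cols": 50,
    "correlation_length": 5,
    "alpha_cov": 0.5,
    "origin_lon": -10,
    "origin_lat": 44,
    "res_arcmin": 5,
    "lat_gradient": 2
  },
  "species": [
    {
      "id": "sp1",
      "beta": {
        "tmax": -1.6,
        "pan": 0.6,
        "broadleaf": 0.6,
        "crop": -0.3
      },
      "beta_sq": {
        "tmax": -0.8
      },
      "intercept": -0.5,
      "detection_gamma": 0.5,
      "n_target": 400
    },
    {
      "id": "sp2",
      "beta": {
        "tmax": -1.2,
        "pan": 0.6,
        "broadleaf": 0.9,
        "crop": -0.3
      },
      "beta_sq": {
        "tmax": -0.8
      },
      "intercept": -0.5,
      "detection_gamma": 0.5,
      "n_target": 400
    },
    {
      "id": "sp3",
      "beta": {
        "tmax": -2,
        "pan": 0.6,
        "broadleaf": 0.4,
        "crop": -0.3
      },
      "beta_sq": {
        "tmax": -0.8
      },
      "intercept": -0.5,
      "detection_gamma": 0.5,
      "n_target": 400
    }
  ],
  "scenarios": [
    {
      "name": "SSP1-2.6",
      "gcm_label": "IPSL",
      "delta": {
        "tmin": 1.4,
        "tmax": 1.4,
        "pan": 0.92,
        "needleleaf": 0.3,
        "broadleaf": 0.3,
        "grassland": -0.25,
        "shrub": -0.25,
        "crop": 0.2
      }
    },
    {
      "name": "SSP2-4.5",
      "gcm_label": "IPSL",
      "delta": {
        "tmin": 2.2,
        "tmax": 2.2,
        "pan": 0.88,
        "grassland": -0.1,
        "shrub": -0.1,
        "crop": 0.15
      }
    }
  ],
  "modes": ["both", "clim", "land"],
  "settings": {
    "bandwidth_cells": 10,
    "n_pseudoabsences": 10000,
    "q": 0.05,
    "boyce_windows": 101,
    "boyce_frac": 0.1,
    "n_biomes": 3,
    "n_hubs": 15,
    "n_trees": 200,
    "importance_reps": 3
  },
  "seed": 1
}
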