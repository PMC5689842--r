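{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "cryodose study report",
  "type": "object",
  "required": [
    "seed",
    "package_version",
    "calibration",
    "per_angle",
    "correction_factor",
    "validation",
    "gamma_params",
    "n_clip_warnings"
  ],
  "properties": {
    "seed": { "type": "integer" },
    "package_version": { "type": "string" },
    "calibration": {
      "type": "object",
      "required": ["bolus", "film"],
      "properties": {
        "bolus": {
          "type": "object",
          "required": ["slope", "slope_se", "intercept", "n"]
        },
        "film": {
          "type": "object",
          "required": ["points", "dose_range"]
        }
      }
    },
    "per_angle": {
      "type": "array",
      "items": {
        "type": "object",
        "required": [
          "gantry_angle_deg", "mean_ratio", "ratio_sd", "n_pixels",
          "profile_diff_inline_pct", "profile_diff_crossline_pct"
        ]
      }
    },
    "correction_factor": {
      "type": "object",
      "required": ["k", "k_sd", "angle_subset", "direction"]
    },
    "validation": {
      "type": "array",
      "items": {
        "type": "object",
        "required": [
          "arrangement", "pass_rate_pct", "n_evaluated", "max_gamma",
          "profile_diff_inline_pct", "profile_diff_crossline_pct"
        ]
      }
    },
    "gamma_params": {
      "type": "object",
      "required": [
        "dose_criterion_pct", "dta_mm", "low_dose_threshold_pct",
        "search_radius_factor", "search_step_fraction"
      ]
    },
    "n_clip_warnings": { "type": "integer" }
  }
}
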