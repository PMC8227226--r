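{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "voltmip-report",
  "title": "voltmip pipeline report",
  "type": "object",
  "additionalProperties": false,
  "required": ["meta"],
  "anyOf": [
    {"required": ["mechanism"]},
    {"required": ["screening"]},
    {"required": ["calibration"]},
    {"required": ["validation"]}
  ],
  "properties": {
    "meta": {
      "type": "object",
      "required": ["schema_version", "package"],
      "properties": {
        "schema_version": {"type": "string"},
        "package": {"type": "string"},
        "package_version": {"type": "string"}
      }
    },
    "config": {"type": "object"},
    "mechanism": {
      "type": "object",
      "required": ["alpha_n", "alpha", "n_electrons", "control_regime",
                   "proton_coupled", "fits"],
      "properties": {
        "alpha_n": {"type": "number"},
        "alpha": {"type": "number"},
        "n_electrons": {"type": "number"},
        "n_electrons_int": {"type": "integer"},
        "control_regime": {"enum": ["diffusion", "mixed", "adsorption"]},
        "proton_coupled": {"type": "boolean"},
        "reference_scan_rate": {"type": "number"},
        "fits": {"type": "object"}
      }
    },
    "screening": {
      "type": "object",
      "required": ["table", "selected_monomer"],
      "properties": {
        "table": {"type": "object"},
        "selected_monomer": {"type": "string"},
        "runner_up": {"type": ["string", "null"]},
        "units": {"type": ["string", "null"]},
        "ratio": {"type": "object"}
      }
    },
    "calibration": {
      "type": "object",
      "required": ["slope", "sigma_blank", "lod", "loq"],
      "properties": {
        "slope": {"type": "number"},
        "intercept": {"type": "number"},
        "r_squared": {"type": "number"},
        "sigma_blank": {"type": "number"},
        "sigma_source": {"enum": ["blank_replicates", "fit_residuals"]},
        "lod": {"type": "number"},
        "loq": {"type": "number"},
        "linear_range": {"type": "array"},
        "usable": {"type": "boolean"}
      }
    },
    "validation": {
      "type": "object",
      "required": ["calibration", "recovery"],
      "properties": {
        "calibration": {"type": "object"},
        "precision": {"type": "object"},
        "recovery": {"type": "object"},
        "interference": {"type": "object"},
        "max_interference_pct": {"type": "number"},
        "comparison": {"type": "object"}
      }
    }
  }
}
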