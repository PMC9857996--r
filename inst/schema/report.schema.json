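{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "specbind pipeline report",
  "type": "object",
  "required": ["package", "version", "config_checksum", "stages"],
  "properties": {
    "package": {"type": "string", "const": "specbind"},
    "version": {"type": "string"},
    "config_checksum": {"type": "string"},
    "seed": {"type": ["integer", "null"]},
    "stages": {
      "type": "object",
      "properties": {
        "binding": {
          "type": "object",
          "required": ["I0", "I_inf", "n", "K_per_M", "rss"],
          "properties": {
            "I0": {"type": "number"},
            "I_inf": {"type": "number"},
            "n": {"type": "number", "exclusiveMinimum": 0},
            "K_per_M": {"type": "number", "exclusiveMinimum": 0},
            "stderr_n": {"type": ["number", "null"]},
            "stderr_K": {"type": ["number", "null"]},
            "rss": {"type": "number", "minimum": 0},
            "warnings": {"type": "array", "items": {"type": "string"}}
          }
        },
        "peaks": {
          "type": "object",
          "required": ["reference_peak_nm", "treated_peak_nm", "shift_nm"],
          "properties": {
            "reference_peak_nm": {"type": "number"},
            "treated_peak_nm": {"type": "number"},
            "shift_nm": {"type": "number"}
          }
        },
        "fret": {
          "type": "object",
          "required": ["J_M1cm1nm4", "R0_nm", "E", "r_nm",
                       "valid_r_lt_7nm", "valid_range"],
          "properties": {
            "J_M1cm1nm4": {"type": "number", "minimum": 0},
            "J_cm3_M1": {"type": "number", "minimum": 0},
            "R0_nm": {"type": "number", "minimum": 0},
            "E": {"type": "number", "minimum": 0, "maximum": 1},
            "r_nm": {"type": "number", "minimum": 0},
            "valid_r_lt_7nm": {"type": "boolean"},
            "valid_range": {"type": "boolean"},
            "convention": {"enum": ["standard_A6", "paper_literal"]}
          }
        },
        "kinetics": {
          "type": "object",
          "required": ["baseline", "treated"],
          "properties": {
            "baseline": {
              "type": "object",
              "required": ["v0_nM_per_min", "released_uM"]
            },
            "treated": {
              "type": "array",
              "items": {
                "type": "object",
                "required": ["label", "v0_nM_per_min", "released_uM",
                             "percent_decrease"]
              }
            }
          }
        },
        "calibration": {
          "type": "object",
          "required": ["reference", "others"],
          "properties": {
            "reference": {
              "type": "object",
              "required": ["slope_per_uM", "intercept", "r2"]
            },
            "others": {
              "type": "array",
              "items": {
                "type": "object",
                "required": ["label", "slope_per_uM", "equivalent"]
              }
            }
          }
        }
      }
    }
  }
}
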