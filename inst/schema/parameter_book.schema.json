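{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "nanoflow parameter book (book.yaml + referenced CSV tables)",
  "description": "Schema of the YAML master file written/read by write_parameter_book()/read_parameter_book(). The referenced CSV tables are documented under 'definitions'.",
  "type": "object",
  "required": ["substances", "trend", "regional", "fate", "sim", "geometry", "files"],
  "properties": {
    "substances": {
      "type": "array", "minItems": 1, "items": {"type": "string"}
    },
    "trend": {
      "type": "object",
      "required": ["breakpoint_year", "median_rate_pre", "median_rate_post", "relative_spread"],
      "properties": {
        "breakpoint_year": {"type": "integer"},
        "median_rate_pre": {"type": "number", "exclusiveMinimum": -100},
        "median_rate_post": {"type": "number", "exclusiveMinimum": -100},
        "relative_spread": {"type": "number", "minimum": 0, "exclusiveMaximum": 1}
      }
    },
    "regional": {
      "type": "object",
      "required": ["domestic_demand", "world_gdp"],
      "properties": {
        "domestic_demand": {"type": "number", "minimum": 0},
        "world_gdp": {"type": "number", "exclusiveMinimum": 0}
      }
    },
    "fate": {
      "type": "object",
      "required": ["incineration_elimination", "sea_export_fraction", "settling_fresh", "settling_marine", "sludge_to_soil", "stp_removal"],
      "additionalProperties": {"$ref": "#/definitions/distribution"}
    },
    "sim": {
      "type": "object",
      "required": ["year_start", "year_end", "reference_year", "n_iterations", "seed"],
      "properties": {
        "year_start": {"type": "integer"},
        "year_end": {"type": "integer"},
        "reference_year": {"type": "integer"},
        "n_iterations": {"type": "integer", "minimum": 1},
        "seed": {"type": "integer"},
        "production_sampling": {"enum": ["linear", "log"]}
      }
    },
    "geometry": {
      "type": "object",
      "description": "All entries strictly positive; sewer_connection_fraction in [0,1]. Units: volumes m3 or m3/a, areas m2, depths m, densities kg/m3, air_exchange_rate 1/a.",
      "additionalProperties": {"type": "number", "exclusiveMinimum": 0}
    },
    "files": {
      "type": "object",
      "required": ["applications", "transfers", "estimates"],
      "additionalProperties": {"type": "string"}
    }
  },
  "definitions": {
    "distribution": {
      "type": "object",
      "required": ["family", "params"],
      "properties": {
        "family": {"enum": ["point", "uniform", "triangular", "trapezoidal", "lognormal"]},
        "params": {"type": "object"},
        "support": {"type": "array", "minItems": 2, "maxItems": 2, "items": {"type": "number"}}
      }
    },
    "applications.csv": {
      "description": "One row per application. Columns: id, substance, start_year, lifespan_m (integer >= 1), share_family, share_p1..share_p4 (family parameters in declaration order), share_support_low, share_support_high.",
      "type": "object"
    },
    "transfers.csv": {
      "description": "One row per (application, phase, compartment) transfer coefficient. Columns: application_id, phase (production|use|eol), compartment, family, p1..p4, support_low, support_high. EOL coefficients of an application must have central values summing to 1.",
      "type": "object"
    },
    "estimates.csv": {
      "description": "Production volume estimates. Columns: substance, source_tag, low, high (t/a, low == high for point estimates), year (the estimate's own reference year).",
      "type": "object"
    },
    "endpoints.csv": {
      "description": "Ecotoxicological endpoints. Columns: species, endpoint_kind (acute_effect|chronic_effect|acute_noec|chronic_noec), concentration (> 0), unit, source_tag, optional substance.",
      "type": "object"
    }
  }
}
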