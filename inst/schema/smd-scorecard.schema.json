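{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "smd-scorecard/v1",
  "title": "Synthetic Medical Data Scorecard",
  "type": "object",
  "required": ["schema", "sections", "footer_note"],
  "properties": {
    "schema": {"const": "smd-scorecard/v1"},
    "footer_note": {"type": "string"},
    "failure_notes": {"type": "array", "items": {"type": "string"}},
    "params": {"type": "object"},
    "sections": {
      "type": "object",
      "required": [
        "section_1_general", "section_2_quality", "section_3_task",
        "section_4_human", "section_5_ethics", "section_6_usage",
        "section_7_generation", "section_8_reference"
      ],
      "additionalProperties": false,
      "properties": {
        "section_1_general": {
          "type": "object",
          "required": ["name", "release_date", "version_history",
                       "dataset_size", "dataset_modality", "dataset_provenance",
                       "dataset_intended_use", "dataset_labels",
                       "attribution_licensing", "point_of_contact"]
        },
        "section_2_quality": {
          "type": "object",
          "required": ["congruence", "coverage", "constraint", "completeness",
                       "compliance", "comprehension", "consistency"],
          "additionalProperties": false,
          "properties": {
            "congruence": {"$ref": "#/$defs/criterion"},
            "coverage": {"$ref": "#/$defs/criterion"},
            "constraint": {"$ref": "#/$defs/criterion"},
            "completeness": {"$ref": "#/$defs/criterion"},
            "compliance": {"$ref": "#/$defs/criterion"},
            "comprehension": {"$ref": "#/$defs/criterion"},
            "consistency": {"$ref": "#/$defs/criterion"}
          }
        },
        "section_3_task": {
          "type": "object",
          "required": ["task_performance", "task_specific_metrics"]
        },
        "section_4_human": {
          "type": "object",
          "required": ["human_study_design", "reader_study_results",
                       "observations_failure_cases"]
        },
        "section_5_ethics": {
          "type": "object",
          "required": ["privacy_anonymization", "biases", "limitations",
                       "recommendations"]
        },
        "section_6_usage": {
          "type": "object",
          "required": ["repository_access", "preprocessing_requirements",
                       "user_documentation", "intended_audience"]
        },
        "section_7_generation": {
          "type": "object",
          "required": ["generation_method", "training_validation_process"]
        },
        "section_8_reference": {
          "type": "object",
          "required": ["purpose", "origin_source", "dataset_size",
                       "clinical_population", "acquisition_devices",
                       "reference_standard", "ground_truth_labels",
                       "metadata", "preprocessing", "known_limitations"]
        }
      }
    }
  },
  "$defs": {
    "criterion": {
      "type": "object",
      "required": ["status"],
      "oneOf": [
        {
          "properties": {
            "status": {"const": "computed"},
            "score": {"type": "number", "minimum": 0, "maximum": 1},
            "label": {"enum": ["good", "moderate", "low"]},
            "method": {"enum": ["arithmetic", "geometric"]},
            "weights": {"type": "array", "items": {"type": "number"}},
            "metrics": {
              "type": "array",
              "items": {
                "type": "object",
                "required": ["name", "raw_value"],
                "properties": {
                  "name": {"type": "string"},
                  "raw_value": {"type": ["number", "string"]},
                  "normalized": {"type": "number", "minimum": 0, "maximum": 1},
                  "direction": {"enum": ["maximize", "minimize", "band",
                                          "stat_sig", "unspecified"]},
                  "per_subgroup": {"type": "object"},
                  "params": {"type": "object"}
                }
              }
            }
          },
          "required": ["status", "score", "label", "metrics"]
        },
        {
          "properties": {
            "status": {"const": "not-applicable"},
            "reason": {"type": "string", "minLength": 1}
          },
          "required": ["status", "reason"]
        }
      ]
    }
  }
}
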