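{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "kiddi dialogue corpus",
  "type": "object",
  "required": ["dialogues"],
  "properties": {
    "dialogues": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id", "disease", "turns"],
        "properties": {
          "id": {"type": "string"},
          "disease": {"type": "string"},
          "turns": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["speaker", "text", "symptoms"],
              "properties": {
                "speaker": {"enum": ["patient", "doctor"]},
                "text": {"type": "string"},
                "intent": {
                  "enum": ["Symptom", "Affirmative"],
                  "description": "Patient turns only. 'Symptom' requires a non-empty symptom list; 'Affirmative' (bare agreement with the doctor) requires an empty one."
                },
                "symptoms": {"type": "array", "items": {"type": "string"}}
              }
            },
            "description": "Turns strictly alternate patient/doctor starting with the patient; the first turn is the self-report."
          }
        }
      }
    },
    "symptom_vocab": {
      "type": "array",
      "items": {"type": "string"},
      "description": "Optional superset vocabulary; must contain every symptom mentioned in the dialogues. Rebuilt lexicographically from the dialogues when absent."
    },
    "disease_vocab": {"type": "array", "items": {"type": "string"}}
  }
}
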