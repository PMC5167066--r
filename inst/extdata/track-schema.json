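{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "structmapr canonical-sequence feature track document",
  "type": "object",
  "required": ["accession", "length", "tracks"],
  "properties": {
    "accession": {"type": "string"},
    "length": {"type": "integer"},
    "tracks": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["name", "provenance", "color_hint", "features"],
        "properties": {
          "name": {"type": "string"},
          "provenance": {
            "type": "string",
            "enum": ["UniProt", "PDB", "computed", "user"]
          },
          "color_hint": {"type": "string"},
          "features": {
            "type": "array",
            "items": {
              "type": "object",
              "required": ["start", "end", "type", "label", "attributes"],
              "properties": {
                "start": {"type": "integer"},
                "end": {"type": "integer"},
                "type": {
                  "type": "string",
                  "enum": ["exon", "variant", "pdb_coverage", "mismatch",
                           "modification", "domain", "user"]
                },
                "label": {"type": "string"},
                "attributes": {"type": "object"}
              }
            }
          }
        }
      }
    }
  }
}
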