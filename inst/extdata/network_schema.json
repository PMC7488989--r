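{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "comention JSON export",
  "type": "object",
  "required": ["anddigest", "network"],
  "properties": {
    "anddigest": {"type": "array", "items": {"$ref": "#/definitions/digest"}},
    "network": {
      "type": "object",
      "required": ["nodes", "edges"],
      "properties": {
        "nodes": {"type": "array", "items": {"$ref": "#/definitions/node"}},
        "edges": {"type": "array", "items": {"$ref": "#/definitions/edge"}}
      }
    }
  },
  "definitions": {
    "digest": {
      "type": "object",
      "required": ["pmid", "date", "digest_score", "citations", "mapped_text"],
      "properties": {
        "pmid": {"type": "string"},
        "date": {"type": "integer"},
        "digest_score": {"type": "number"},
        "citations": {"type": "integer"},
        "mapped_text": {"type": "string"}
      }
    },
    "node": {
      "type": "object",
      "required": ["id", "label", "synonyms", "type", "colour", "size",
                   "trend_strength", "mention_count", "x", "y"],
      "properties": {
        "id": {"type": "integer"},
        "label": {"type": "string"},
        "synonyms": {"type": "string"},
        "type": {"type": "string"},
        "colour": {"type": "string"},
        "size": {"type": "number"},
        "trend_strength": {"type": "integer"},
        "mention_count": {"type": "integer"},
        "x": {"type": "number"},
        "y": {"type": "number"}
      }
    },
    "edge": {
      "type": "object",
      "required": ["id", "source", "target", "colour", "size", "s_score",
                   "z_score", "p_value", "template_flag"],
      "properties": {
        "id": {"type": "integer"},
        "source": {"type": "integer"},
        "target": {"type": "integer"},
        "colour": {"type": "string"},
        "size": {"type": "number"},
        "s_score": {"type": "number"},
        "z_score": {"type": "number"},
        "p_value": {"type": "number"},
        "template_flag": {"type": "boolean"}
      }
    }
  }
}
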