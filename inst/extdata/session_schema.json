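{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "phenoscreen session signals",
  "description": "One app administration: frame-wise behavioral signals plus event logs. Versioned; written/read by write_session_json()/read_session_json().",
  "type": "object",
  "required": ["schema_version", "meta", "frames", "name_calls", "touches", "layout"],
  "properties": {
    "schema_version": {"const": "1.0"},
    "meta": {
      "type": "object",
      "required": ["fps"],
      "properties": {
        "fps": {"type": "number", "exclusiveMinimum": 0,
                "description": "frame rate, Hz (app records at 30)"},
        "speaker_turn": {"type": "number",
                         "description": "conversation speaker-turn length, s"},
        "seed": {"type": "integer"}
      }
    },
    "frames": {
      "type": "array",
      "description": "one element per camera frame, in time order",
      "items": {
        "type": "object",
        "required": ["t", "segment", "class", "valid"],
        "properties": {
          "t": {"type": "number", "description": "seconds from session start"},
          "segment": {"type": "string"},
          "class": {"enum": ["social", "nonsocial", "conversation", "game"]},
          "valid": {"type": "boolean",
                    "description": "false = frame invalidated (dropout); never deleted"},
          "gaze_x": {"type": ["number", "null"],
                     "description": "screen coords, origin top-left, x rightward, normalized"},
          "gaze_y": {"type": ["number", "null"]},
          "yaw": {"type": "number", "description": "head pose, degrees"},
          "pitch": {"type": "number"},
          "roll": {"type": "number"},
          "eye_openness": {"type": ["number", "null"], "minimum": 0, "maximum": 1},
          "mouth_y": {"type": ["number", "null"],
                      "description": "mouth-region landmark centroid trace"},
          "brow_y": {"type": ["number", "null"],
                     "description": "eyebrow-region landmark centroid trace"}
        }
      }
    },
    "name_calls": {
      "type": "array", "minItems": 3, "maxItems": 3,
      "description": "the child's name is called exactly three times",
      "items": {
        "type": "object",
        "required": ["onset", "offset"],
        "properties": {
          "onset": {"type": "number"}, "offset": {"type": "number"},
          "respond": {"type": "boolean", "description": "scripted ground truth"},
          "delay": {"type": "number", "description": "scripted offset-to-turn delay, s"}
        }
      }
    },
    "touches": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["t", "x", "y", "popped"],
        "properties": {
          "t": {"type": "number"}, "x": {"type": "number"}, "y": {"type": "number"},
          "popped": {"type": "boolean"},
          "force": {"type": "number", "description": "device force units"},
          "traj_length": {"type": "number", "description": "screen units"},
          "bubble_x": {"type": ["number", "null"],
                       "description": "nearest bubble center at touch time; null = no bubble on screen"},
          "bubble_y": {"type": ["number", "null"]}
        }
      }
    },
    "layout": {
      "type": "array",
      "description": "stimulus layout: full movie schedule (kept intact under degradation), split-screen social halves",
      "items": {
        "type": "object",
        "required": ["name", "class", "duration", "t0"],
        "properties": {
          "name": {"type": "string"},
          "class": {"enum": ["social", "nonsocial", "conversation", "game"]},
          "duration": {"type": "number"}, "t0": {"type": "number"},
          "split_screen": {"type": ["boolean", "null"]},
          "social_half": {"enum": ["left", "right", null]}
        }
      }
    },
    "dropped_segments": {"type": "array", "items": {"type": "string"}}
  }
}
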