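{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ambientsom evaluation report",
  "type": "object",
  "required": ["study", "fid_objects", "noise_std_generated", "snr_ho",
               "snr_ho_reference", "snr_ho_convention", "n_samples",
               "extractor", "seeds"],
  "properties": {
    "study": {"type": "string"},
    "fid_objects": {"type": "number", "minimum": 0},
    "fid_measurement_components": {"type": ["number", "null"]},
    "noise_std_generated": {"type": "number", "minimum": 0},
    "noise_std_reference": {"type": "number", "minimum": 0},
    "snr_ho": {"type": "number", "minimum": 0},
    "snr_ho_reference": {"type": "number", "minimum": 0},
    "snr_ho_convention": {"type": "string", "enum": ["sqrt"]},
    "n_samples": {"type": "integer", "minimum": 1},
    "extractor": {"type": "string"},
    "seeds": {"type": "object"},
    "model_hash": {"type": "string"}
  }
}
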