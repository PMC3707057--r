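{
  "name": "adni_table1",
  "description": "Expert-derived incidence between ten ADNI neuropsychological measures and five cognitive functions. Episodic memory is a single leveled function (levels 0-3, level 3 = delayed recall with distractors, level 2 = shorter-duration recall such as AVLT List B, level 1 = immediate recall / word recognition, level 0 = none); word fluency, selective attention, cognitive flexibility and perceptual motor speed are binary. Selective attention is required by every measure. Measures marked at several episodic-memory levels require the highest marked level; lower levels are implied by the hierarchy.",
  "functions": [
    {"name": "episodic_memory", "kind": "leveled",
     "levels": ["level0", "level1", "level2", "level3"]},
    {"name": "word_fluency", "kind": "binary"},
    {"name": "selective_attention", "kind": "binary"},
    {"name": "cognitive_flexibility", "kind": "binary"},
    {"name": "perceptual_motor_speed", "kind": "binary"}
  ],
  "measures": [
    {"name": "adas_delayed_recall", "direction": "lower",
     "requires": [{"function": "episodic_memory", "level": "level3"},
                  {"function": "selective_attention", "level": "high"}]},
    {"name": "adas_word_recognition", "direction": "lower",
     "requires": [{"function": "episodic_memory", "level": "level1"},
                  {"function": "selective_attention", "level": "high"}]},
    {"name": "avlt_trial6", "direction": "higher",
     "requires": [{"function": "episodic_memory", "level": "level3"},
                  {"function": "selective_attention", "level": "high"}]},
    {"name": "avlt_listb", "direction": "higher",
     "requires": [{"function": "episodic_memory", "level": "level2"},
                  {"function": "selective_attention", "level": "high"}]},
    {"name": "boston_naming", "direction": "higher",
     "requires": [{"function": "word_fluency", "level": "high"},
                  {"function": "selective_attention", "level": "high"}]},
    {"name": "category_fluency", "direction": "higher",
     "requires": [{"function": "word_fluency", "level": "high"},
                  {"function": "selective_attention", "level": "high"},
                  {"function": "cognitive_flexibility", "level": "high"}]},
    {"name": "adas_number_cancellation", "direction": "lower",
     "requires": [{"function": "selective_attention", "level": "high"}]},
    {"name": "trail_making_a", "direction": "lower",
     "requires": [{"function": "selective_attention", "level": "high"},
                  {"function": "perceptual_motor_speed", "level": "high"}]},
    {"name": "trail_making_b", "direction": "lower",
     "requires": [{"function": "selective_attention", "level": "high"},
                  {"function": "cognitive_flexibility", "level": "high"},
                  {"function": "perceptual_motor_speed", "level": "high"}]},
    {"name": "wais_digit_symbol", "direction": "higher",
     "requires": [{"function": "selective_attention", "level": "high"},
                  {"function": "perceptual_motor_speed", "level": "high"}]}
  ]
}
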