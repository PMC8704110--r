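{
  "name": "example-anxiety-negation",
  "categories": {
    "negate": ["no", "not", "never", "nothing"],
    "anx": ["worried", "fearful", "nervous", "tense", "worr*"],
    "sad": ["crying", "grief", "sad", "tears"],
    "death": ["bury", "coffin", "kill", "dead"]
  }
}
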