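{
  "pre_triggers": ["no", "not", "negative", "normal"],
  "post_triggers": ["negative", "normal"],
  "window": 5
}
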