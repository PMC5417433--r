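{
  "exp1_pooled": {"stage": "bark", "successes": 532, "total": 840, "percent": 63.3},
  "exp2_pooled": {"stage": "phloem", "successes": 951, "total": 1123, "percent": 84.7},
  "exp3_pooled": {"stage": "brood", "successes": 590, "total": 840, "percent": 70.2}
}
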