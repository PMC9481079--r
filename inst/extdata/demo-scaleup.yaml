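schema_version: '1.0'
kind: scenario
name: demo scale-up
targets:
  ebf_promotion: 0.9
  ors: 0.9
  pneumonia_abx: 0.9
  clean_delivery: 0.9
scale_up_start: 1
scale_up_end: 5
shape: linear
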