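tr: 3.0
max_scans: 238
lead_in: 6.0
rest: 21.0
conditions:
- label: easy
  onsets:
  - 6.0
  - 120.0
  - 234.0
  - 348.0
  - 462.0
  - 576.0
  duration: 36.0
- label: hard
  onsets:
  - 63.0
  - 177.0
  - 291.0
  - 405.0
  - 519.0
  - 633.0
  duration: 36.0
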