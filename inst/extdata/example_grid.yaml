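# Scenario grid: instrument strength (weak/mod/strong) by confounding
# level (low/med/high), cohort size n. `regime: balanced` switches to the
# high-exposure preset.
- strength: weak
  confounding: high
  n: 30000
- strength: strong
  confounding: high
  n: 30000
- strength: weak
  confounding: high
  n: 30000
  regime: balanced
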