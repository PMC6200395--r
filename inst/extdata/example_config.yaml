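# Example configuration: default cell with doubled KCC2 conductance and a
# ten-minute simulation window.
g_kcc2_uS_cm2: 40
sim:
  duration_ms: 600000
  record_every_ms: 1000
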