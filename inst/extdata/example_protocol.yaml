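# Example protocol: switch the ATPase off over 15 min (from t = 10 min)
# and back on over 15 min (from t = 55 min).
- kind: pump_ramp
  direction: "off"
  start_ms: 600000
  stop_ms: 1500000
- kind: pump_ramp
  direction: "on"
  start_ms: 3300000
  stop_ms: 4200000
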