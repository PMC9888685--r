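# Variable schema for the standard input CSV layout.
variables:
  - {name: time_days, role: time, scale: continuous}
  - {name: event, role: event, scale: nominal}
  - {name: race, role: focus, scale: nominal}
  - {name: tract_id, role: tract, scale: nominal}
  - {name: z1, role: individual, scale: continuous}
  - {name: z2, role: individual, scale: continuous}
  - {name: z3, role: individual, scale: continuous}
  - {name: w, role: contextual, scale: continuous}
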