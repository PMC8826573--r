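# Curated strand/loop ranges for the kappa light-chain constant domain,
# EU numbering. Anchors: V133 (charge-pair site) in strand B; the AB
# loop carries the conserved salt bridge to the CH1 G strand; S176/F116
# engineering sites fall in EF/A.
kind: CL-kappa
elements:
  A: [[114, 119]]
  AB: [[120, 123]]
  B: [[124, 134]]
  BC: [[135, 137]]
  C: [[138, 144]]
  CD: [[145, 149]]
  D: [[150, 157]]
  DE: [[158, 162]]
  E: [[163, 173]]
  EF: [[174, 177]]
  F: [[178, 187]]
  FG: [[188, 193]]
  G: [[194, 212]]
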