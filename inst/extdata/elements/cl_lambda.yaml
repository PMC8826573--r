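# Curated strand/loop ranges for the lambda light-chain constant domain
# (Kabat-style numbering). Topology as for the kappa isotype.
kind: CL-lambda
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
  G: [[194, 211]]
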