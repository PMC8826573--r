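# Curated strand/loop ranges for the light-chain variable domain, Kabat
# numbering; C'/C'' hairpin folded into CD as for VH.
kind: VL
elements:
  A: [[3, 12]]
  AB: [[13, 16]]
  B: [[17, 24]]
  BC: [[25, 34]]
  C: [[35, 38]]
  CD: [[39, 60]]
  D: [[61, 65]]
  DE: [[66, 69]]
  E: [[70, 76]]
  EF: [[77, 84]]
  F: [[85, 90]]
  FG: [[91, 96]]
  G: [[97, 106]]
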