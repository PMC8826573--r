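# Curated strand/loop ranges for the heavy-chain variable domain, Kabat
# numbering. The variable-domain fold has 9 strands; the extra C'/C''
# hairpin is folded into the CD segment here so that the shared A-G
# label set applies to both constant and variable domains.
kind: VH
elements:
  A: [[3, 12]]
  AB: [[13, 16]]
  B: [[17, 25]]
  BC: [[26, 35]]
  C: [[36, 39]]
  CD: [[40, 66]]
  D: [[67, 71]]
  DE: [[72, 75]]
  E: [[76, 82]]
  EF: [[83, 87]]
  F: [[88, 96]]
  FG: [[97, 102]]
  G: [[103, 112]]
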