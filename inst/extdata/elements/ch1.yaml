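# Curated strand/loop ranges for the IgG1 CH1 domain, EU numbering.
# Anchors: S183 (charge-pair engineering site) in strand E; the
# C-terminal strand G carries the residues salt-bridging the CL AB loop.
kind: CH1
elements:
  A: [[122, 128]]
  AB: [[129, 132]]
  B: [[133, 139]]
  BC: [[140, 145]]
  C: [[146, 152]]
  CD: [[153, 159]]
  D: [[160, 167]]
  DE: [[168, 172]]
  E: [[173, 184]]
  EF: [[185, 186]]
  F: [[187, 194]]
  FG: [[195, 199]]
  G: [[200, 213]]
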