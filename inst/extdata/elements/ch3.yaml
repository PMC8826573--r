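# Curated strand/loop ranges for the IgG1 CH3 domain, EU numbering.
# Approximate reconstruction of the standard c-type Ig topology
# (strands A-G, 3+4 sheet sandwich); anchored on well-described
# interface residues: Y407 in strand E, E356/E357 in the AB loop,
# K439 in strand G, K370 in strand B, D399 in the DE loop, K392 in
# strand D. Ranges are regenerable with assignStrands() on a CH3
# crystal structure.
kind: CH3
elements:
  A: [[342, 351]]
  AB: [[352, 357]]
  B: [[358, 370]]
  BC: [[371, 371]]
  C: [[372, 379]]
  CD: [[380, 384]]
  D: [[385, 392]]
  DE: [[393, 399]]
  E: [[400, 409]]
  EF: [[410, 413]]
  F: [[414, 422]]
  FG: [[423, 427]]
  G: [[428, 445]]
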