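# Membrane topology annotation for human AQP2 (author numbering).
# Helix boundaries are curated approximations consistent with the
# structural-element labels of the packaged variant catalogue; NPA motifs,
# the ar/R selectivity filter and the C-tail phosphosites are as described
# for AQP2.
helix_ranges:
  H1: [12, 35]
  H2: [40, 64]
  HB: [66, 74]
  H3: [94, 115]
  H4: [126, 150]
  H5: [155, 180]
  HE: [184, 193]
  H6: [198, 218]
loops:
  loop A: [36, 39]
  loop C: [116, 125]
  loop D: [151, 154]
  loop E: [181, 183]
c_tail_start: 223
phosphosites: [256, 261]
npa_residues: [68, 69, 70, 184, 185, 186]
arR_residues: [174, 187]
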