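# Minimal library design used in examples and tests.
# L3: 3 positions over {Y,S,G}; H1/H2: two binary Y/S positions;
# H3: variable length 2-3 over {Y,S,W}.
cdrs:
  L3:
    lengths: [3]
    positions:
      "3":
        - [TAT, TCT, GGT]
        - [TAT, TCT, GGT]
        - [TAT, TCT, GGT]
  H1:
    lengths: [2]
    positions:
      "2":
        - [TAT, TCT]
        - [TAT, TCT]
  H2:
    lengths: [2]
    positions:
      "2":
        - [TAT, TCT]
        - [TAT, TCT]
  H3:
    lengths: [2, 3]
    codon_set: [TAT, TCT, TGG]
anchors:
  L3: {left: GGTTCTAC, right: TTCGGCCA}
  H1: {left: TTCGGCCA, right: TGGGTGCG}
  H2: {left: TGGGTGCG, right: CGTTTCAC}
  H3: {left: CGTTTCAC, right: TGGGGTCA}
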