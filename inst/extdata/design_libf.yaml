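# Restricted-diversity synthetic Fab library design.
# H1 carries six binary degenerate codons (64 unique sequences) and H2 eight
# (256 unique sequences). L3 (3-7 codons) and H3 (1-17 codons) are encoded by
# nine codons for nine amino acids at every diversified position, giving
# theoretical diversities of order 1e9 and 1e16. Codon identities are a
# stand-in composition drawn from residues observed in published clones; the
# true oligonucleotide tables of the source library are proprietary, so any
# composition-dependent analysis should load its own design document.
cdrs:
  L3:
    lengths: [3, 4, 5, 6, 7]
    codon_set: [TAT, TCT, GGT, TGG, TTT, CAT, CCT, GTT, GCT]
  H1:
    lengths: [6]
    positions:
      "6":
        - [ATT, TCT]
        - [TCT, TAT]
        - [TCT, TAT]
        - [TCT, TAT]
        - [GGT, TCT]
        - [ATT, ATG]
  H2:
    lengths: [8]
    positions:
      "8":
        - [TCT, TAT]
        - [CCT, TCT]
        - [ATT, TCT]
        - [TAT, TCT]
        - [TCT, GGT]
        - [TAT, TCT]
        - [ACT, TCT]
        - [TAT, TCT]
  H3:
    lengths: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17]
    codon_set: [TAT, TCT, GGT, TGG, TTT, CAT, CCT, GTT, GCT]
anchors:
  L3: {left: GGTGGTTCTGGTAC, right: TTCGGCCAAGGGAC}
  H1: {left: TTCGGCCAAGGGAC, right: TGGGTGCGTCAGGC}
  H2: {left: TGGGTGCGTCAGGC, right: CGTTTCACTATAAG}
  H3: {left: CGTTTCACTATAAG, right: TGGGGTCAAGGAAC}
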