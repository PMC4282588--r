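# SYNTHETIC subpocket definition for the toy dimer trajectories built
# by gen_trajectory(): residues 1..20 per chain, grouped into four
# five-residue subpockets, protomers = chains A and B with shared
# numbering.
#
# The S1-S4 interface residue lists used for real caspases (the
# binding-site grouping credited to Yoshimori and co-workers) are not
# shipped with this package; this file is a reconstructed stand-in and
# an editable template. Replace resno lists and protomer chain ids
# with your own binding-site definition before analysing real
# structures.
subpockets:
  S1: [1, 2, 3, 4, 5]
  S2: [6, 7, 8, 9, 10]
  S3: [11, 12, 13, 14, 15]
  S4: [16, 17, 18, 19, 20]
protomers:
  A: A
  B: B
offsets:
  A: 0
  B: 0
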