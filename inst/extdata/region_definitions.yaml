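# Default region definitions (1-based positions in the mature-protein
# reference numbering of each family). These position lists are editable
# defaults, not authoritative annotations: the TCR-exposed helix subsets
# follow a solvent-exposure convention and should be adjusted to the
# alignment in use. CDR positions follow the IMGT unique numbering.
TRAV:
  CDR1: [27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38]
  CDR2: [56, 57, 58, 59, 60, 61, 62, 63, 64, 65]
TRBV:
  CDR1: [27, 28, 29, 30, 31, 32, 33, 34, 35, 36, 37, 38]
  CDR2: [56, 57, 58, 59, 60, 61, 62, 63, 64, 65]
HLA-I:
  # TCR-exposed residues of the alpha-1 helix
  helix1: [58, 61, 62, 65, 66, 68, 69, 72, 73, 76, 79, 80, 83]
  # TCR-exposed residues of the alpha-2 helix
  helix2: [142, 145, 146, 149, 150, 151, 154, 155, 158, 162, 163, 166, 167, 170]
  # peptide-contacting residues (non-TCR-facing comparison set)
  peptide_contacts: [5, 7, 9, 24, 25, 33, 34, 45, 59, 63, 64, 67, 70, 74, 77, 81, 84, 95, 97, 99, 114, 116, 123, 143, 147, 152, 156, 159, 160, 164, 171]
HLA-IIa:
  # TCR-exposed residues of the class II alpha-chain helix
  # (solvent-exposure heuristic)
  helix1: [55, 58, 59, 62, 63, 66, 67, 70, 71, 74, 75, 78]
HLA-IIb:
  # TCR-exposed residues of the class II beta-chain helix
  helix2: [60, 63, 64, 67, 68, 71, 72, 75, 76, 79, 80, 83]
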