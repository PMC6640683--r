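# Domain map for a four-chain IgG (e.g. the murine IgG2a crystal structure
# 1IGT: light chains A and C, heavy chains B and D, author numbering).
#
# ASSUMPTIONS, not crystallographic fact:
#   - Domain boundaries are approximate canonical IgG boundaries; adjust to
#     the deposited SEQRES/author numbering of the structure in hand.
#   - The four anchor residues (Fab-left Asp31, Fab-right Lys65, hinge
#     Cys225, Fc Phe442) are placed on the heavy chains, with the left Fab
#     carried by chain B and the right Fab by chain D. The source structure
#     does not fix this chain assignment; verify against the molecule
#     before interpreting left/right angle signs.
fragments:
  - {label: VL_A,  chain: A, start: 1,   end: 108}
  - {label: CL_A,  chain: A, start: 109, end: 214}
  - {label: VL_C,  chain: C, start: 1,   end: 108}
  - {label: CL_C,  chain: C, start: 109, end: 214}
  - {label: VH_B,  chain: B, start: 1,   end: 118}
  - {label: CH1_B, chain: B, start: 119, end: 220}
  - {label: linker_B, chain: B, start: 221, end: 230}
  - {label: CH2_B, chain: B, start: 231, end: 340}
  - {label: CH3_B, chain: B, start: 341, end: 444}
  - {label: VH_D,  chain: D, start: 1,   end: 118}
  - {label: CH1_D, chain: D, start: 119, end: 220}
  - {label: linker_D, chain: D, start: 221, end: 230}
  - {label: CH2_D, chain: D, start: 231, end: 340}
  - {label: CH3_D, chain: D, start: 341, end: 444}
regions:
  fab_left:  [VH_B, CH1_B, VL_A, CL_A]
  fab_right: [VH_D, CH1_D, VL_C, CL_C]
  fc:        [CH2_B, CH3_B, CH2_D, CH3_D]
anchors:
  fab_left:  {chain: B, resid: 31,  rule: CA}   # Asp 31
  fab_right: {chain: D, resid: 65,  rule: CA}   # Lys 65
  hinge:     {chain: B, resid: 225, rule: CA}   # Cys 225 (CH1-CH2 linker)
  fc:        {chain: B, resid: 442, rule: CA}   # Phe 442
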