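# Default gbcrispr configuration.
#
# Enzyme geometry: spacer_len is the number of nt between the recognition
# 3' end and the top-strand cut; negative values place the cut inside the
# recognition site (ordinary palindromic enzymes). overhang_len is the length
# of the 5' overhang produced.
#
# All 4-nt fusion sites below are editable. The part-syntax boundaries follow
# the plant common-syntax standard; the CRISPR-specific codes (B3c, B5c, B5d),
# the braid overhangs, the entry-vector sockets and the polycistron slot
# boundaries are package defaults.
enzymes:
  - {name: BsaI,    recognition: GGTCTC, spacer_len: 1,  overhang_len: 4}
  - {name: BsmBI,   recognition: CGTCTC, spacer_len: 1,  overhang_len: 4}
  - {name: SpeI,    recognition: ACTAGT, spacer_len: -5, overhang_len: 4}
  - {name: BamHI,   recognition: GGATCC, spacer_len: -5, overhang_len: 4}
  - {name: EcoRI,   recognition: GAATTC, spacer_len: -5, overhang_len: 4}
  - {name: HindIII, recognition: AAGCTT, spacer_len: -5, overhang_len: 4}

syntax:
  A1:  {left: GGAG, right: TGAC}
  A2:  {left: TGAC, right: TCCC}
  A3:  {left: TCCC, right: TACT}
  B1:  {left: TACT, right: CCAT}
  B2:  {left: CCAT, right: AATG}
  B3:  {left: AATG, right: AGCC}
  B3c: {left: ATTG, right: AGCC}
  B4:  {left: AGCC, right: TTCG}
  B5:  {left: TTCG, right: GCTT}
  B5c: {left: TTCG, right: GCTT}
  B5d: {left: TTCG, right: GCAA}
  B6:  {left: GCTT, right: GGTA}
  C1:  {left: GGTA, right: CGCT}

# edges of any transcriptional unit = the alpha-vector BsaI sockets
tu_edges: {left: GGAG, right: CGCT}

# pUPD-like entry vector BsmBI sockets
entry_sockets: {left: CTCG, right: CTCA}

# the braid: alpha plasmids release their cargo with BsmBI using e1/mid/e3
# (position 1 = e1..mid, position 2 = mid..e3; omega destinations expose
# e1/e3); omega plasmids release with BsaI using the omega trio, whose outer
# edges coincide with the alpha BsaI sockets so products re-enter the loop.
braid:
  alpha: {e1: CGGT, mid: AGTG, e3: CGTA}
  omega: {e1: GGAG, mid: ACGG, e3: CGCT}

# 2-D multiplexing: duplex_sockets are the BsmBI overhangs between the tRNA
# and the scaffold inside every level -1 plasmid (slot-independent duplex
# chemistry); slot_boundaries are the left BsaI fusion sites of slots 1..k,
# the last slot of a design always closing on the C1 right edge (CGCT).
poly:
  duplex_sockets: {left: GTGT, right: GCGA}
  slot_boundaries: [ATTG, ACCT, CAGC, TGGA, AGAC]

# monocistronic D/M-Target fusion span: B3c left .. B5c right / B5d right
target_modes:
  monocistronic_D: {left: ATTG, right: GCTT}
  monocistronic_M: {left: ATTG, right: GCAA}

sequences:
  # canonical SpCas9 sgRNA scaffold
  scaffold: GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC
  # pre-tRNA-Gly spacer used by the rice polycistronic strategy
  trna: AACAAAGCACCAGTGGTCTAGTGGTAGAATAGTACCCTGCCACGGTACAGACCCGGGTTCGATTCCCGGCTGGTGCA
  promoters:
    # synthetic stand-in for the Arabidopsis U6-26 PolIII promoter
    U6-26: CTTACCATAAGAGGACTTGTGGTTTGGCGAGCTTGCAATACATGGGGCCACAGTAGCGCGCACTTTGCGGAGGTCCTACTCACTCGAGGC

policies:
  policy_5G: substitute        # reject | substitute
  cycle_cap_fragments: 10      # max fragments per ligation cycle
  cycle_cap_products: 50       # max enumerated products before erroring
  rounding: half_up            # mutation-rate rounding, one decimal
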