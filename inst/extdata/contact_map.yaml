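# Curated peptide/MHC-I contact map (9-mer register).
# Per allele, per peptide position: one-letter identities of the MHC pocket
# residues contacting that position, distilled from published class I
# structures; an empty string marks a solvent-exposed (TCR-facing) position.
# Pocket compositions follow the canonical anchor architecture of each
# allele: H2-Db P5/P9, H2-Kb P5/P8, HLA-A*02:01 P2/P9, HLA-B*07:02 P2/P9.
k: 9
alleles:
  H2-Kb:
    1: "YYRE"
    2: "EKYY"
    3: "YRNY"
    4: "R"
    5: "YFWINQS"
    6: "WA"
    7: "LR"
    8: "YDTLWS"
    9: "YTKW"
  H2-Db:
    1: "YYRT"
    2: "EKNY"
    3: "YNSF"
    4: ""
    5: "QNYWSM"
    6: "WR"
    7: "H"
    8: "TL"
    9: "YFLWSV"
  HLA-A0201:
    1: "YWTE"
    2: "MFEKVY"
    3: "YRH"
    4: "E"
    5: "QW"
    6: "VWR"
    7: "TRW"
    8: "K"
    9: "YLDTVW"
  HLA-B0702:
    1: "YWRE"
    2: "NYESQ"
    3: "YNR"
    4: ""
    5: "QR"
    6: "WID"
    7: "SRW"
    8: "E"
    9: "YLSTFW"
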