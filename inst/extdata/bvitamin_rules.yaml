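# Default producer rules for the eight B-vitamin biosynthesis pathways.
#
# Grammar: each vitamin has one or more rule lines.  A line is a
# '+'-separated conjunction of terms; a term is a single role/subset id or
# a parenthesised OR-group "(A or B)".  A genome is a predicted producer of
# a vitamin iff at least one line is satisfied, or (where a tolerance is
# declared) a line fails only by missing at most `max_missing` of the
# `tolerable` roles while all `mandatory` roles are present.
#
# Compound mnemonics (e.g. BioFADB) are conjunctive subsets of atomic
# roles; a subset id counts as present in a genome iff every member role
# is annotated.  Subset membership is editable: CbiKX and CobAT are kept
# as single (bifunctional) roles here because their decomposition is
# pathway-variant dependent.
subsets:
  BioFADB: [BioF, BioA, BioD, BioB]
  CbiGF:   [CbiG, CbiF]
  CbiLGF:  [CbiL, CbiG, CbiF]
  CbiECA:  [CbiE, CbiC, CbiA]
  CbiPB:   [CbiP, CbiB]
  CobNST:  [CobN, CobS, CobT]
  CobUS:   [CobU, CobS]
  FolEBKP: [FolE, FolB, FolK, FolP]
  PdxBFAJH: [PdxB, PdxF, PdxA, PdxJ, PdxH]
  PdxTS:   [PdxT, PdxS]
  ThiGSF:  [ThiG, ThiS, ThiF]
  ThiCDE:  [ThiC, ThiD, ThiE]
vitamins:
  biotin:
    lines:
      - "BioW + BioFADB"
      - "BioC + BioFADB"
  cobalamin:
    # aerobic route first, anaerobic second
    lines:
      - "CbiL + CobG + CbiGF + (CobF or CbiD) + CbiECA + CobNST + CobAT + CbiPB + CobUS"
      - "(CbiKX or CysG) + CbiLGF + (CobF or CbiD) + CbiECA + CobAT + CbiPB + CobUS"
  folate:
    # production of DHF or THF suffices; pabAa/pabAb are not essential,
    # pabAc is.  FolQ is commonly missing from annotations and is
    # therefore not in the essential list.
    lines:
      - "FolEBKP + pabAc + DHFS + DHFR + FPGS"
  niacin:
    lines:
      - "ASPOX + QSYN + QAPRT + NaMNAT + NADS"
  pantothenate:
    # active form is CoA; a single missing enzyme in the branched part of
    # the pathway is tolerated, but PBAL (and the CoA steps) are mandatory.
    lines:
      - "KPHMT + KPRED + ASPDC + PBAL + PANK + PPCS + PPCDC + DPCK"
    tolerance:
      tolerable: [KPHMT, KPRED, ASPDC]
      max_missing: 1
    mandatory: [PBAL, PANK, PPCS, PPCDC, DPCK]
  pyridoxine:
    lines:
      - "dxs + gapA + PdxBFAJH"
      - "PdxTS"
  riboflavin:
    # PyrP is commonly missing from annotations and is not essential.
    lines:
      - "GTPCH2 + PyrDR + DHBPS + DMRLS + RSA + RK + FMNAT"
  thiamin:
    # thiamin monophosphate production suffices for producer status
    lines:
      - "(ThiH or ThiO) + ThiGSF + ThiCDE"
      - "Thi4 + ThiCDE"
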