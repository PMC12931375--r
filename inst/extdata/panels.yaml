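# Default spot-scoring panels.  Positivity rule per panel: a spot is
# positive when at least k_required genes each have raw count >= min_count
# (both default to 1).
isg:
  genes: [IFIT1, USP18, MX1, IFI27, IFI44L, OAS1]
ifnb1:
  genes: [IFNB1]
apoptosis:
  genes: [CASP3, CASP8, BAX, BAK1, CYCS]
necroptosis:
  genes: [RIPK1, MLKL]
zbp1:
  genes: [ZBP1]
tgfb:
  genes: [TGFB1]
anchor_cd68:
  genes: [CD68]
# M1/M2 orientation follows the immunohistochemistry convention
# (CD16 = FCGR3A as M1, CD163 as M2); see load_panels(m_orientation=).
m1_markers:
  genes: [FCGR3A, FCGR1A]
m2_markers:
  genes: [CD163, ARG1]
m1_cytokines:
  genes: [IL1B, TNF, IL12B, IL18]
m2_cytokines:
  genes: [IL10, ARG1, TGFB1]
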