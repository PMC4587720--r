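# Default drug-metabolizing-enzyme gene panel: 55 cytochrome P450 genes and
# 62 phase II conjugation genes (17 GST, 10 NAT, 13 SULT, 22 UGT), with the
# eight methylation control genes (four housekeeping, two tumor suppressor,
# two DNA repair) and the housekeeping expression controls.
panel_genes:
  CYP:
    - CYP1A1
    - CYP1A2
    - CYP1B1
    - CYP2A6
    - CYP2A7
    - CYP2A13
    - CYP2B6
    - CYP2C8
    - CYP2C9
    - CYP2C18
    - CYP2C19
    - CYP2D6
    - CYP2E1
    - CYP2F1
    - CYP2J2
    - CYP2R1
    - CYP2S1
    - CYP2U1
    - CYP2W1
    - CYP3A4
    - CYP3A5
    - CYP3A7
    - CYP3A43
    - CYP4A11
    - CYP4A22
    - CYP4B1
    - CYP4F2
    - CYP4F3
    - CYP4F8
    - CYP4F11
    - CYP4F12
    - CYP4F22
    - CYP4V2
    - CYP4X1
    - CYP5A1
    - CYP7A1
    - CYP7B1
    - CYP8A1
    - CYP8B1
    - CYP11A1
    - CYP11B1
    - CYP11B2
    - CYP17A1
    - CYP19A1
    - CYP20A1
    - CYP21A2
    - CYP24A1
    - CYP26A1
    - CYP26B1
    - CYP26C1
    - CYP27A1
    - CYP27B1
    - CYP39A1
    - CYP46A1
    - CYP51A1
  GST:
    - GSTA1
    - GSTA2
    - GSTA3
    - GSTA4
    - GSTA5
    - GSTM1
    - GSTM2
    - GSTM3
    - GSTM4
    - GSTM5
    - GSTP1
    - GSTT1
    - GSTT2
    - GSTZ1
    - GSTO1
    - GSTO2
    - GSTK1
  NAT:
    - NAT1
    - NAT2
    - NAT6
    - NAT8
    - NAT8B
    - NAT8L
    - NAT9
    - NAT10
    - NAT14
    - NAT16
  SULT:
    - SULT1A1
    - SULT1A2
    - SULT1A3
    - SULT1A4
    - SULT1B1
    - SULT1C2
    - SULT1C3
    - SULT1C4
    - SULT1E1
    - SULT2A1
    - SULT2B1
    - SULT4A1
    - SULT6B1
  UGT:
    - UGT1A1
    - UGT1A3
    - UGT1A4
    - UGT1A5
    - UGT1A6
    - UGT1A7
    - UGT1A8
    - UGT1A9
    - UGT1A10
    - UGT2A1
    - UGT2A2
    - UGT2A3
    - UGT2B4
    - UGT2B7
    - UGT2B10
    - UGT2B11
    - UGT2B15
    - UGT2B17
    - UGT2B28
    - UGT3A1
    - UGT3A2
    - UGT8
control_methylation_genes:
  - ACTB
  - B2M
  - GAPDH
  - TBP
  - BMP4
  - IGFBP3
  - MLH1
  - MGMT
control_expression_genes:
  - ACTB
  - B2M
  - GAPDH
  - TBP
isoform_loci:
  UGT1A:
    - isoform: UGT1A1
      transcript_tag: NM_000463
    - isoform: UGT1A3
      transcript_tag: NM_019093
    - isoform: UGT1A4
      transcript_tag: NM_007120
    - isoform: UGT1A5
      transcript_tag: NM_019078
    - isoform: UGT1A6
      transcript_tag: NM_001072
    - isoform: UGT1A7
      transcript_tag: NM_019077
    - isoform: UGT1A8
      transcript_tag: NM_019076
    - isoform: UGT1A9
      transcript_tag: NM_021027
    - isoform: UGT1A10
      transcript_tag: NM_019075
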