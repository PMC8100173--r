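pair_id	ligand	receptor
CXCL1_CXCR1	CXCL1	CXCR1
CXCL1_CXCR2	CXCL1	CXCR2
CXCL2_CXCR1	CXCL2	CXCR1
CXCL2_CXCR2	CXCL2	CXCR2
CXCL3_CXCR2	CXCL3	CXCR2
CXCL8_CXCR1	CXCL8	CXCR1
CXCL8_CXCR2	CXCL8	CXCR2
CXCL12_CXCR4	CXCL12	CXCR4
CXCL9_CXCR3	CXCL9	CXCR3
CXCL10_CXCR3	CXCL10	CXCR3
CCL2_CCR2	CCL2	CCR2
CCL5_CCR5	CCL5	CCR5
CCL13_CCR2	CCL13	CCR2
CXCL5_CXCR2	CXCL5	CXCR2
VEGFA_FLT1	VEGFA	FLT1
VEGFA_KDR	VEGFA	KDR
PDGFA_PDGFRA	PDGFA	PDGFRA
PDGFB_PDGFRB	PDGFB	PDGFRB
FGF1_FGFR1	FGF1	FGFR1
FGF2_FGFR1	FGF2	FGFR1
FGF7_FGFR2	FGF7	FGFR2
TGFB1_TGFBR1	TGFB1	TGFBR1
TGFB1_TGFBR2	TGFB1	TGFBR2
IL6_IL6R	IL6	IL6R
IL1B_IL1R1	IL1B	IL1R1
TNF_TNFRSF1A	TNF	TNFRSF1A
CSF1_CSF1R	CSF1	CSF1R
CSF3_CSF3R	CSF3	CSF3R
EGF_EGFR	EGF	EGFR
AREG_EGFR	AREG	EGFR
HGF_MET	HGF	MET
ANGPT1_TEK	ANGPT1	TEK
ANGPT2_TEK	ANGPT2	TEK
DLL4_NOTCH1	DLL4	NOTCH1
JAG1_NOTCH1	JAG1	NOTCH1
JAG1_NOTCH2	JAG1	NOTCH2
PVR_TIGIT	PVR	TIGIT
PVR_CD226	PVR	CD226
PVR_CD96	PVR	CD96
CD274_PDCD1	CD274	PDCD1
CD80_CTLA4	CD80	CTLA4
CD86_CTLA4	CD86	CTLA4
LGALS9_HAVCR2	LGALS9	HAVCR2
CD70_CD27	CD70	CD27
TNFSF13B_TNFRSF13B	TNFSF13B	TNFRSF13B
EFNA1_EPHA2	EFNA1	EPHA2
SEMA3A_NRP1	SEMA3A	NRP1
NAMPT_INSR	NAMPT	INSR
MIF_CD74	MIF	CD74
SPP1_CD44	SPP1	CD44
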