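cell_type	gene
B-cells	BLK
B-cells	CD19
B-cells	FCRL2
B-cells	MS4A1
B-cells	KIAA0125
B-cells	TNFRSF17
B-cells	TCL1A
B-cells	SPIB
B-cells	PNOC
CD45	PTPRC
Cytotoxic cells	PRF1
Cytotoxic cells	GZMA
Cytotoxic cells	GZMB
Cytotoxic cells	NKG7
Cytotoxic cells	GZMH
Cytotoxic cells	KLRK1
Cytotoxic cells	KLRB1
Cytotoxic cells	KLRD1
Cytotoxic cells	CTSW
Cytotoxic cells	GNLY
DC	CCL13
DC	CD209
DC	HSD11B1
Exhausted CD8	LAG3
Exhausted CD8	CD244
Exhausted CD8	EOMES
Exhausted CD8	PTGER4
Macrophages	CD68
Macrophages	CD84
Macrophages	CD163
Macrophages	MS4A4A
Mast cells	TPSB2
Mast cells	TPSAB1
Mast cells	CPA3
Mast cells	MS4A2
Mast cells	HDC
Neutrophils	FPR1
Neutrophils	SIGLEC5
Neutrophils	CSF3R
Neutrophils	FCAR
Neutrophils	FCGR3B
Neutrophils	CEACAM3
Neutrophils	S100A12
NK CD56dim cells	KIR2DL3
NK CD56dim cells	KIR3DL1
NK CD56dim cells	KIR3DL2
NK CD56dim cells	IL21R
NK cells	XCL1
NK cells	XCL2
NK cells	NCR1
T-cells	CD6
T-cells	CD3D
T-cells	CD3E
T-cells	SH2D1A
T-cells	TRAT1
T-cells	CD3G
Th1 cells	TBX21
Treg	FOXP3
CD8 T cells	CD8A
CD8 T cells	CD8B
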