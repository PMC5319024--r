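cell_type	n_candidates	n_selected	mean_similarity	single_gene	note
B-cells	34	9	0.59	FALSE
CD45	1	1	NA	TRUE	single-gene marker; PTPRC (alias PTRPC accepted)
Cytotoxic cells	18	10	0.69	FALSE
DC	7	3	0.46	FALSE
Exhausted CD8	5	4	0.44	FALSE
Macrophages	33	4	0.71	FALSE
Mast cells	31	5	0.74	FALSE
Neutrophils	32	7	0.48	FALSE
NK CD56dim cells	14	4	0.40	FALSE
NK cells	36	3	0.47	FALSE
T-cells	13	6	0.81	FALSE
Th1 cells	27	1	NA	TRUE	single-gene marker; TBX21 (T-bet)
Treg	18	1	NA	TRUE	single-gene marker; FOXP3
CD8 T cells	35	2	0.51	FALSE
CD4 cells	20	0	NA	FALSE	derived score: T-cells minus CD8 T cells
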