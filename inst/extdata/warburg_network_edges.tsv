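source	target	relation
SLC2A1	glucose	transport
SLC2A3	glucose	transport
SLC2A5	fructose	transport
SLC16A1	lactate	transport
SLC16A3	lactate	transport
glucose	glucose_6_phosphate	conversion
HK1	glucose_6_phosphate	catalysis
HK2	glucose_6_phosphate	catalysis
HK3	glucose_6_phosphate	catalysis
GCK	glucose_6_phosphate	catalysis
glucose_6_phosphate	glucose	conversion
G6PC	glucose	catalysis
G6PC2	glucose	catalysis
G6PC3	glucose	catalysis
glucose_6_phosphate	fructose_6_phosphate	conversion
GPI	fructose_6_phosphate	catalysis
fructose_6_phosphate	fructose_1_6_bisphosphate	conversion
PFKL	fructose_1_6_bisphosphate	catalysis
PFKM	fructose_1_6_bisphosphate	catalysis
PFKP	fructose_1_6_bisphosphate	catalysis
fructose_6_phosphate	fructose_2_6_bisphosphate	conversion
PFKFB1	fructose_2_6_bisphosphate	catalysis
PFKFB2	fructose_2_6_bisphosphate	catalysis
PFKFB3	fructose_2_6_bisphosphate	catalysis
PFKFB4	fructose_2_6_bisphosphate	catalysis
fructose_1_6_bisphosphate	fructose_6_phosphate	conversion
FBP1	fructose_6_phosphate	catalysis
FBP2	fructose_6_phosphate	catalysis
fructose_1_6_bisphosphate	glyceraldehyde_3_phosphate	conversion
fructose_1_6_bisphosphate	dihydroxyacetone_phosphate	conversion
ALDOA	glyceraldehyde_3_phosphate	catalysis
ALDOB	glyceraldehyde_3_phosphate	catalysis
ALDOC	glyceraldehyde_3_phosphate	catalysis
dihydroxyacetone_phosphate	glyceraldehyde_3_phosphate	conversion
TPI1	glyceraldehyde_3_phosphate	catalysis
glyceraldehyde_3_phosphate	bisphosphoglycerate_1_3	conversion
GAPDH	bisphosphoglycerate_1_3	catalysis
bisphosphoglycerate_1_3	phosphoglycerate_3	conversion
PGK1	phosphoglycerate_3	catalysis
phosphoglycerate_3	phosphoglycerate_2	conversion
PGAM1	phosphoglycerate_2	catalysis
PGAM2	phosphoglycerate_2	catalysis
phosphoglycerate_2	phosphoenolpyruvate	conversion
ENO1	phosphoenolpyruvate	catalysis
ENO2	phosphoenolpyruvate	catalysis
ENO3	phosphoenolpyruvate	catalysis
phosphoenolpyruvate	pyruvate	conversion
PKM	pyruvate	catalysis
PKLR	pyruvate	catalysis
pyruvate	lactate	conversion
LDHA	lactate	catalysis
LDHB	lactate	catalysis
pyruvate	acetyl_coa	conversion
PDHA1	acetyl_coa	catalysis
PDHA2	acetyl_coa	catalysis
PDHB	acetyl_coa	catalysis
DLAT	acetyl_coa	catalysis
PDHX	acetyl_coa	catalysis
DLD	acetyl_coa	catalysis
PDK1	PDHA1	regulation
PDK2	PDHA1	regulation
PDK3	PDHA1	regulation
PDK4	PDHA1	regulation
pyruvate	oxaloacetate	conversion
PC	oxaloacetate	catalysis
oxaloacetate	phosphoenolpyruvate	conversion
PCK1	phosphoenolpyruvate	catalysis
PCK2	phosphoenolpyruvate	catalysis
malate	oxaloacetate	conversion
MDH1	oxaloacetate	catalysis
MDH2	oxaloacetate	catalysis
fructose	fructose_1_phosphate	conversion
KHK	fructose_1_phosphate	catalysis
fructose_1_phosphate	glyceraldehyde_3_phosphate	conversion
fructose_1_phosphate	dihydroxyacetone_phosphate	conversion
ALDOB	dihydroxyacetone_phosphate	catalysis
phosphoglycerate_3	phosphohydroxypyruvate_3	conversion
PHGDH	phosphohydroxypyruvate_3	catalysis
phosphohydroxypyruvate_3	phosphoserine_3	conversion
PSAT1	phosphoserine_3	catalysis
phosphoserine_3	serine	conversion
PSPH	serine	catalysis
serine	glycine	conversion
SHMT1	glycine	catalysis
glucose_6_phosphate	phosphogluconolactone_6	conversion
G6PD	phosphogluconolactone_6	catalysis
phosphogluconolactone_6	phosphogluconate_6	conversion
PGLS	phosphogluconate_6	catalysis
phosphogluconate_6	ribulose_5_phosphate	conversion
PGD	ribulose_5_phosphate	catalysis
ribulose_5_phosphate	ribose_5_phosphate	conversion
RPIA	ribose_5_phosphate	catalysis
ribulose_5_phosphate	xylulose_5_phosphate	conversion
RPE	xylulose_5_phosphate	catalysis
ribose_5_phosphate	sedoheptulose_7_phosphate	conversion
xylulose_5_phosphate	glyceraldehyde_3_phosphate	conversion
TKT	sedoheptulose_7_phosphate	catalysis
TKTL1	sedoheptulose_7_phosphate	catalysis
TKTL2	sedoheptulose_7_phosphate	catalysis
sedoheptulose_7_phosphate	erythrose_4_phosphate	conversion
erythrose_4_phosphate	fructose_6_phosphate	conversion
TALDO1	erythrose_4_phosphate	catalysis
oxaloacetate	citrate	conversion
CS	citrate	catalysis
citrate	isocitrate	conversion
ACO2	isocitrate	catalysis
isocitrate	oxoglutarate_2	conversion
IDH2	oxoglutarate_2	catalysis
IDH3A	oxoglutarate_2	catalysis
IDH3B	oxoglutarate_2	catalysis
IDH3G	oxoglutarate_2	catalysis
oxoglutarate_2	succinyl_coa	conversion
OGDH	succinyl_coa	catalysis
DLST	succinyl_coa	catalysis
succinyl_coa	succinate	conversion
SUCLG1	succinate	catalysis
SUCLG2	succinate	catalysis
SUCLA2	succinate	catalysis
succinate	fumarate	conversion
SDHA	fumarate	catalysis
SDHB	fumarate	catalysis
SDHC	fumarate	catalysis
SDHD	fumarate	catalysis
fumarate	malate	conversion
FH	malate	catalysis
citrate	acetyl_coa	conversion
ACLY	acetyl_coa	catalysis
acetyl_coa	malonyl_coa	conversion
ACACA	malonyl_coa	catalysis
ACACB	malonyl_coa	catalysis
malonyl_coa	palmitate	conversion
FASN	palmitate	catalysis
glutamine	glutamate	conversion
GLS	glutamate	catalysis
GLS2	glutamate	catalysis
glutamate	oxoglutarate_2	conversion
GLUD1	oxoglutarate_2	catalysis
glutamate	aspartate	conversion
GOT1	aspartate	catalysis
GOT2	aspartate	catalysis
malate	pyruvate	conversion
ME1	pyruvate	catalysis
ME2	pyruvate	catalysis
oxoglutarate_2	isocitrate	conversion
IDH1	isocitrate	catalysis
isocitrate	citrate	conversion
ACO1	citrate	catalysis
HNRNPA1	PKM	splicing_regulation
HNRNPA2B1	PKM	splicing_regulation
PTBP1	PKM	splicing_regulation
PTBP2	PKM	splicing_regulation
VHL	SLC2A1	regulation
VHL	LDHA	regulation
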