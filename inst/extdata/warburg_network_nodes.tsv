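id	kind	label	pathways
SLC2A1	gene	GLUT1 glucose transporter	transporters|glycolysis
SLC2A3	gene	GLUT3 glucose transporter	transporters|glycolysis
SLC2A5	gene	GLUT5 fructose transporter	transporters|fructose
HK1	gene	hexokinase 1	glycolysis
HK2	gene	hexokinase 2	glycolysis
HK3	gene	hexokinase 3	glycolysis
GCK	gene	glucokinase	glycolysis
GPI	gene	glucose-6-phosphate isomerase	glycolysis|gluconeogenesis
PFKL	gene	phosphofructokinase liver type	glycolysis
PFKM	gene	phosphofructokinase muscle type	glycolysis
PFKP	gene	phosphofructokinase platelet type	glycolysis
PFKFB1	gene	6-phosphofructo-2-kinase/fructose-2,6-bisphosphatase 1	glycolysis
PFKFB2	gene	6-phosphofructo-2-kinase/fructose-2,6-bisphosphatase 2	glycolysis
PFKFB3	gene	6-phosphofructo-2-kinase/fructose-2,6-bisphosphatase 3	glycolysis
PFKFB4	gene	6-phosphofructo-2-kinase/fructose-2,6-bisphosphatase 4	glycolysis
ALDOA	gene	aldolase A	glycolysis
ALDOB	gene	aldolase B	glycolysis|gluconeogenesis|fructose
ALDOC	gene	aldolase C	glycolysis
TPI1	gene	triosephosphate isomerase	glycolysis|gluconeogenesis
GAPDH	gene	glyceraldehyde-3-phosphate dehydrogenase	glycolysis|gluconeogenesis
PGK1	gene	phosphoglycerate kinase 1	glycolysis|gluconeogenesis
PGAM1	gene	phosphoglycerate mutase 1	glycolysis|gluconeogenesis
PGAM2	gene	phosphoglycerate mutase 2	glycolysis|gluconeogenesis
ENO1	gene	enolase 1 (alpha)	glycolysis|gluconeogenesis
ENO2	gene	enolase 2 (gamma, neuronal)	glycolysis|gluconeogenesis
ENO3	gene	enolase 3 (beta)	glycolysis|gluconeogenesis
PKM	gene	pyruvate kinase M1/M2	glycolysis
PKLR	gene	pyruvate kinase L/R	glycolysis
VHL	gene	von Hippel-Lindau tumor suppressor	glycolysis
G6PC	gene	glucose-6-phosphatase catalytic 1	gluconeogenesis
G6PC2	gene	glucose-6-phosphatase catalytic 2	gluconeogenesis
G6PC3	gene	glucose-6-phosphatase catalytic 3	gluconeogenesis
FBP1	gene	fructose-1,6-bisphosphatase 1	gluconeogenesis
FBP2	gene	fructose-1,6-bisphosphatase 2	gluconeogenesis
PC	gene	pyruvate carboxylase	gluconeogenesis
PCK1	gene	phosphoenolpyruvate carboxykinase 1 (cytosolic)	gluconeogenesis
PCK2	gene	phosphoenolpyruvate carboxykinase 2 (mitochondrial)	gluconeogenesis
MDH1	gene	malate dehydrogenase 1 (cytosolic)	gluconeogenesis
KHK	gene	ketohexokinase	fructose
PHGDH	gene	phosphoglycerate dehydrogenase	serine_glycine
PSAT1	gene	phosphoserine aminotransferase 1	serine_glycine
PSPH	gene	phosphoserine phosphatase	serine_glycine
SHMT1	gene	serine hydroxymethyltransferase 1	serine_glycine
G6PD	gene	glucose-6-phosphate dehydrogenase	ppp
PGLS	gene	6-phosphogluconolactonase	ppp
PGD	gene	phosphogluconate dehydrogenase	ppp
RPIA	gene	ribose-5-phosphate isomerase A	ppp
RPE	gene	ribulose-5-phosphate-3-epimerase	ppp
TKT	gene	transketolase	ppp
TKTL1	gene	transketolase like 1	ppp
TKTL2	gene	transketolase like 2	ppp
TALDO1	gene	transaldolase 1	ppp
LDHA	gene	lactate dehydrogenase A	pyruvate_metabolism
LDHB	gene	lactate dehydrogenase B	pyruvate_metabolism
SLC16A1	gene	MCT1 monocarboxylate transporter	transporters|pyruvate_metabolism
SLC16A3	gene	MCT4 monocarboxylate transporter	transporters|pyruvate_metabolism
PDK1	gene	pyruvate dehydrogenase kinase 1	pyruvate_metabolism
PDK2	gene	pyruvate dehydrogenase kinase 2	pyruvate_metabolism
PDK3	gene	pyruvate dehydrogenase kinase 3	pyruvate_metabolism
PDK4	gene	pyruvate dehydrogenase kinase 4	pyruvate_metabolism
PDHA1	gene	pyruvate dehydrogenase E1 alpha 1	pyruvate_metabolism
PDHA2	gene	pyruvate dehydrogenase E1 alpha 2	pyruvate_metabolism
PDHB	gene	pyruvate dehydrogenase E1 beta	pyruvate_metabolism
DLAT	gene	dihydrolipoamide S-acetyltransferase (PDH E2)	pyruvate_metabolism
PDHX	gene	pyruvate dehydrogenase complex component X	pyruvate_metabolism
DLD	gene	dihydrolipoamide dehydrogenase	pyruvate_metabolism|tca
CS	gene	citrate synthase	tca
ACO2	gene	aconitase 2 (mitochondrial)	tca
IDH2	gene	isocitrate dehydrogenase (NADP+) 2	tca
IDH3A	gene	isocitrate dehydrogenase 3 alpha	tca
IDH3B	gene	isocitrate dehydrogenase 3 beta	tca
IDH3G	gene	isocitrate dehydrogenase 3 gamma	tca
OGDH	gene	oxoglutarate dehydrogenase	tca
DLST	gene	dihydrolipoamide S-succinyltransferase	tca
SUCLG1	gene	succinate-CoA ligase alpha	tca
SUCLG2	gene	succinate-CoA ligase GDP-forming beta	tca
SUCLA2	gene	succinate-CoA ligase ADP-forming beta	tca
SDHA	gene	succinate dehydrogenase A	tca
SDHB	gene	succinate dehydrogenase B	tca
SDHC	gene	succinate dehydrogenase C	tca
SDHD	gene	succinate dehydrogenase D	tca
FH	gene	fumarate hydratase	tca
MDH2	gene	malate dehydrogenase 2 (mitochondrial)	tca
ACLY	gene	ATP citrate lyase	fatty_acid_synthesis
ACACA	gene	acetyl-CoA carboxylase alpha	fatty_acid_synthesis
ACACB	gene	acetyl-CoA carboxylase beta	fatty_acid_synthesis
FASN	gene	fatty acid synthase	fatty_acid_synthesis
GLS	gene	glutaminase (kidney type)	glutaminolysis
GLS2	gene	glutaminase 2 (liver type)	glutaminolysis
GLUD1	gene	glutamate dehydrogenase 1	glutaminolysis
GOT1	gene	aspartate aminotransferase (cytosolic)	glutaminolysis
GOT2	gene	aspartate aminotransferase (mitochondrial)	glutaminolysis
ME1	gene	malic enzyme 1 (cytosolic)	glutaminolysis
ME2	gene	malic enzyme 2 (mitochondrial)	glutaminolysis
IDH1	gene	isocitrate dehydrogenase (NADP+) 1 (cytosolic)	glutaminolysis
ACO1	gene	aconitase 1 (cytosolic)	glutaminolysis
HNRNPA1	gene	heterogeneous nuclear ribonucleoprotein A1	pkm_splicing
HNRNPA2B1	gene	heterogeneous nuclear ribonucleoprotein A2/B1	pkm_splicing
PTBP1	gene	polypyrimidine tract binding protein 1	pkm_splicing
PTBP2	gene	polypyrimidine tract binding protein 2	pkm_splicing
glucose	metabolite	glucose	glycolysis
glucose_6_phosphate	metabolite	glucose 6-phosphate	glycolysis
fructose_6_phosphate	metabolite	fructose 6-phosphate	glycolysis
fructose_1_6_bisphosphate	metabolite	fructose 1,6-bisphosphate	glycolysis
fructose_2_6_bisphosphate	metabolite	fructose 2,6-bisphosphate	glycolysis
dihydroxyacetone_phosphate	metabolite	dihydroxyacetone phosphate	glycolysis
glyceraldehyde_3_phosphate	metabolite	glyceraldehyde 3-phosphate	glycolysis
bisphosphoglycerate_1_3	metabolite	1,3-bisphosphoglycerate	glycolysis
phosphoglycerate_3	metabolite	3-phosphoglycerate	glycolysis
phosphoglycerate_2	metabolite	2-phosphoglycerate	glycolysis
phosphoenolpyruvate	metabolite	phosphoenolpyruvate	glycolysis
pyruvate	metabolite	pyruvate	glycolysis|pyruvate_metabolism
lactate	metabolite	lactate	pyruvate_metabolism
acetyl_coa	metabolite	acetyl-CoA	pyruvate_metabolism|fatty_acid_synthesis
citrate	metabolite	citrate	tca
isocitrate	metabolite	isocitrate	tca
oxoglutarate_2	metabolite	2-oxoglutarate	tca|glutaminolysis
succinyl_coa	metabolite	succinyl-CoA	tca
succinate	metabolite	succinate	tca
fumarate	metabolite	fumarate	tca
malate	metabolite	malate	tca
oxaloacetate	metabolite	oxaloacetate	tca|gluconeogenesis
phosphogluconolactone_6	metabolite	6-phosphoglucono-delta-lactone	ppp
phosphogluconate_6	metabolite	6-phosphogluconate	ppp
ribulose_5_phosphate	metabolite	ribulose 5-phosphate	ppp
ribose_5_phosphate	metabolite	ribose 5-phosphate	ppp
xylulose_5_phosphate	metabolite	xylulose 5-phosphate	ppp
sedoheptulose_7_phosphate	metabolite	sedoheptulose 7-phosphate	ppp
erythrose_4_phosphate	metabolite	erythrose 4-phosphate	ppp
phosphohydroxypyruvate_3	metabolite	3-phosphohydroxypyruvate	serine_glycine
phosphoserine_3	metabolite	3-phosphoserine	serine_glycine
serine	metabolite	serine	serine_glycine
glycine	metabolite	glycine	serine_glycine
fructose	metabolite	fructose	fructose
fructose_1_phosphate	metabolite	fructose 1-phosphate	fructose
glutamine	metabolite	glutamine	glutaminolysis
glutamate	metabolite	glutamate	glutaminolysis
aspartate	metabolite	aspartate	glutaminolysis
malonyl_coa	metabolite	malonyl-CoA	fatty_acid_synthesis
palmitate	metabolite	palmitate	fatty_acid_synthesis
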