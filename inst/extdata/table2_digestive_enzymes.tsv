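gene_id	location	enzyme	ec_number	mean_stunting	mean_SAM	mean_adult
PRSS1	pancreatic_protease	Cationic trypsinogen	3.4.21.4	0.2	9.8	0.1
PRSS2	pancreatic_protease	Anionic trypsinogen	3.4.21.4	267.9	168.6	87.2
PRSS3	pancreatic_protease	Mesotrypsinogen	3.4.21.4	133.6	158.1	185.4
PGC	pancreatic_protease	Pepsinogen C	3.4.23.1	40.6	509.7	330.7
CPA2	pancreatic_protease	Pancreatic procarboxypeptidase A2	3.4.17.15	20.7	20.8	16.8
CPA3	pancreatic_protease	Pancreatic procarboxypeptidase A3	3.4.17.1	1.6	2.1	2.3
TMPRSS15	brush_border_protease	Enteropeptidase	3.4.21.9	261.2	91.4	459.6
DPP4	brush_border_protease	Dipeptidylpeptidase IV	3.4.14.5	67.7	31.3	88.3
GGT1	brush_border_protease	Gamma-glutamyl transferase	2.3.2.2	172.2	86.8	128.7
ENPEP	brush_border_protease	Aminopeptidase A	3.4.11.7	49.6	20.3	47.4
ANPEP	brush_border_protease	Aminopeptidase N	3.4.11.2	2391.7	1504.7	3321.1
FOLH1	brush_border_protease	Glutamate carboxypeptidase II, folate hydrolase	3.4.17.21	201.6	134.6	206.1
ACE	brush_border_protease	Angiotensin 1 converting enzyme	3.2.1/3.4.15.1	180.0	107.0	314.5
MME	brush_border_protease	Neprilysin, membrane metalloendopeptidase	3.4.24.11	135.4	62.4	155.6
MEP1B	brush_border_protease	Meprin A	3.4.24.63	146.4	52.3	220.9
ALPI	brush_border_enzyme	Alkaline phosphatase, intestinal	3.1.3.1	1382.1	555.0	1123.0
SI	brush_border_enzyme	Sucrase-isomaltase	3.2.1.20	163.4	50.6	307.2
MGAM	brush_border_enzyme	Maltase-glucoamylase	3.2.1.20	101.6	36.7	102.9
LCT	brush_border_enzyme	Lactase	3.2.1	363.1	87.7	14.0
TREH	brush_border_enzyme	Trehalase	3.2.1.28	177.5	101.9	270.1
LIPF	lipase	Gastric lipase	3.1.1.3	0.2	1.5	7.2
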