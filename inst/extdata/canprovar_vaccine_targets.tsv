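# CanProVar-derived vaccine-target statistics: per-gene counts of
# deleterious/cancer-associated variants (f_D), polymorphism/neutral
# variants (f_P), the published association ratio f_D/f_P (one decimal),
# and protein family annotation (pass-through metadata; NA where none).
target	f_D	f_P	ratio	family
PTEN	389	1	389	NA
TP53	1353	7	193.3	P53_family
CTNNB1	132	1	132	Beta-catenin_family
BRAF	99	1	99	Protein_kinase_superfamily,_TKL_Ser/Thr_protein_kinase_family,_RAF_subfamily
NF2	74	1	74	NA
EGFR	188	3	62.7	Protein_kinase_superfamily,_Tyr_protein_kinase_family,_EGF_receptor_subfamily
SMAD4	107	2	53.5	Dwarfin/SMAD_family
VHL	272	6	45.3	NA
KIT	131	3	43.7	Protein_kinase_superfamily,_Tyr_protein_kinase_family,_CSF-1/PDGF_receptor_subfamily
PIK3CA	174	4	43.5	PI3/PI4-kinase_family
NRAS	36	1	36	Small_GTPase_superfamily,_Ras_family
MSH2	103	5	20.6	DNA_mismatch_repair_MutS_family
GATA1	20	1	20	NA
MLH1	118	6	19.7	DNA_mismatch_repair_MutL/HexB_family
FBXW7	67	4	16.8	NA
MEN1	49	3	16.3	NA
FGFR3	31	2	15.5	Protein_kinase_superfamily,_Tyr_protein_kinase_family,_Fibroblast_growth_factor_receptor_subfamily
TSHR	46	3	15.3	G-protein_coupled_receptor_1_family,_FSH/LSH/TSH_subfamily
JAK2	40	3	13.3	Protein_kinase_superfamily,_Tyr_protein_kinase_family,_JAK_subfamily
RB1	102	8	12.8	Retinoblastoma_protein_(RB)_family
PDGFRA	35	3	11.7	Protein_kinase_superfamily,_Tyr_protein_kinase_family,_CSF-1/PDGF_receptor_subfamily
NF1	65	6	10.8	NA
FGFR2	43	4	10.8	Protein_kinase_superfamily,_Tyr_protein_kinase_family,_Fibroblast_growth_factor_receptor_subfamily
FLT3	35	4	8.8	Protein_kinase_superfamily,_Tyr_protein_kinase_family,_CSF-1/PDGF_receptor_subfamily
CDH1	68	8	8.5	NA
TNFAIP3	31	4	7.8	Peptidase_C64_family
CBL	30	4	7.5	NA
RET	58	8	7.3	Protein_kinase_superfamily,_Tyr_protein_kinase_family
MSH6	40	8	5	DNA_mismatch_repair_MutS_family
ERBB2	29	6	4.8	Protein_kinase_superfamily,_Tyr_protein_kinase_family,_EGF_receptor_subfamily
MET	23	5	4.6	Protein_kinase_superfamily,_Tyr_protein_kinase_family
ABL1	23	7	3.3	Protein_kinase_superfamily,_Tyr_protein_kinase_family,_ABL_subfamily
ALK	27	9	3	Protein_kinase_superfamily,_Tyr_protein_kinase_family,_Insulin_receptor_subfamily
ATM	134	52	2.6	PI3/PI4-kinase_family,_ATM_subfamily
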