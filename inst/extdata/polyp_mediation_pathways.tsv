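exposure_id	mediator_id	outcome_id	beta1	beta2	beta3	mediator_effect_printed	mediated_proportion_printed_pct
Methanobrevibacter	CCR2 on CD62L+ myeloid Dendritic Cell	Nasal polyp	-0.211	-0.076	0.194	0.016	8.33
Holdemania	CCR2 on CD62L+ myeloid Dendritic Cell	Nasal polyp	-0.2	-0.076	-0.144	0.015	-10.57
Candidatus Soleaferrea	CD25 on activated CD4 regulatory T cell	Nasal polyp	0.248	-0.112	0.136	-0.028	-20.31
Methanobrevibacter	CD3 on CD4 regulatory T cell	Nasal polyp	0.26	0.118	0.194	0.031	15.88
RikenellaceaeRC9	CD39 on CD39+ activated CD4 regulatory T cell	Nasal polyp	0.163	0.041	-0.168	0.007	-3.96
Prevotellaceae	CD39 on CD39+ activated CD4 regulatory T cell	Nasal polyp	-0.248	0.041	-0.198	-0.01	5.13
Prevotellaceae	CD45RA on naive CD4+ T cell	Nasal polyp	-0.288	0.035	-0.198	-0.01	5.05
Eubacterium fissicatena	Effector Memory CD8+ T cell %T cell	Nasal polyp	-0.173	-0.047	0.173	0.008	4.74
Deltaproteobacteria	Effector Memory CD8+ T cell %T cell	Nasal polyp	0.274	-0.047	0.246	-0.013	-5.28
Deltaproteobacteria	Terminally Differentiated CD8+ T cell Absolute Count	Nasal polyp	0.31	0.065	0.246	0.02	8.17
Prevotellaceae	Transitional B cell Absolute Count	Nasal polyp	-0.231	-0.059	-0.198	0.014	-6.94
Peptococcaceae	CD14 on Monocytic Myeloid-Derived Suppressor Cells	Gallbladder polyp	-0.325	0.114	0.533	-0.037	-6.94
unknowngenus.id.959	SSC-A on lymphocyte	Gallbladder polyp	-0.189	0.265	-0.713	-0.05	7.02
RuminococcaceaeUCG002	CD24 on IgD- CD38- B cell	Colon polyp	0.222	0.024	0.086	0.005	6.2
RuminococcaceaeUCG002	CD24 on IgD+ CD24+ B cell	Colon polyp	0.304	-0.027	0.086	-0.008	-9.42
Eubacteriumbrachy	CD4 on CD28+ CD4+ T cell	Colon polyp	-0.207	0.039	-0.067	-0.008	12.11
Actinobacteria	CD28+ CD45RA+ CD8dim T cell %CD8dim T cell	Gastric polyp	0.279	0.031	0.263	0.009	3.24
Actinobacteria	CD66b on Granulocytic Myeloid-Derived Suppressor Cells	Gastric polyp	-0.297	0.046	0.263	-0.014	-5.2
Actinobacteria	PDL-1 on CD14+ CD16+ monocyte	Gastric polyp	-0.265	-0.046	0.263	0.012	4.59
Eggerthella	CD33 on CD33+ HLA DR+	Gastric polyp	-0.336	0.028	0.181	-0.01	-5.28
Eggerthella	CD86+ plasmacytoid Dendritic Cell %Dendritic Cell	Gastric polyp	-0.169	0.063	0.181	-0.011	-5.83
Eubacterium oxidoreducens	CD20 on IgD- CD27- B cell	Gastric polyp	0.285	-0.114	-0.262	-0.032	12.4
Eubacterium oxidoreducens	CD28- CD8dim T cell %T cell	Gastric polyp	0.282	0.07	-0.262	0.02	-7.55
Eubacterium oxidoreducens	CD45 on CD66b++ myeloid cell	Gastric polyp	-0.27	0.065	-0.262	-0.018	6.7
Gastranaerophilales	CD45 on CD66b++ myeloid cell	Gastric polyp	0.214	0.065	-0.156	0.014	-8.93
Gastranaerophilales	CD8 on Terminally Differentiated CD8+ T cell	Gastric polyp	0.217	-0.068	-0.156	-0.015	9.46
unknownfamily.id.1000001214	CD45 on CD66b++ myeloid cell	Gastric polyp	0.214	0.065	-0.156	0.014	-8.93
unknownfamily.id.1000001214	CD8 on Terminally Differentiated CD8+ T cell	Gastric polyp	0.217	-0.068	-0.156	-0.015	9.46
unknowngenus.id.1000001215	CD45 on CD66b++ myeloid cell	Gastric polyp	0.214	0.065	-0.156	0.014	-8.93
unknowngenus.id.1000001215	CD8 on Terminally Differentiated CD8+ T cell	Gastric polyp	0.217	-0.068	-0.156	-0.015	9.46
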