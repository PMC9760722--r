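ancestry_group	trait	exposure	gene_id	tier	n_variants	eqtl_tissues	multi_tissue	dexpr_flag	joint2df_flag
AA	HDL	current smoking	POLK	prioritized	5	Heart Left Ventricle,Pancreas,Thyroid	TRUE	FALSE	FALSE
AA	HDL	current smoking	GCNT4	further_prioritized	4	Artery Aorta,Testis	FALSE	TRUE	FALSE
AA	HDL	current smoking	KLK8	prioritized	4	Skin Sun Exposed Lower leg	FALSE	FALSE	FALSE
AA	HDL	current smoking	ANGPT1	prioritized	3	Thyroid	FALSE	FALSE	FALSE
AA	HDL	current smoking	CARM1	prioritized	1	Muscle Skeletal	FALSE	FALSE	TRUE
AA	HDL	current smoking	LIPC	prioritized	1	Liver,Pancreas	FALSE	FALSE	FALSE
AA	HDL	current smoking	YIPF2	prioritized	1	Lung	FALSE	FALSE	TRUE
AA	HDL	ever smoking	PTPRZ1	further_prioritized	21	Artery Aorta	FALSE	TRUE	TRUE
AA	HDL	ever smoking	DNAH7	prioritized	1	Adipose Visceral Omentum,Pancreas,Thyroid	TRUE	FALSE	FALSE
AA	LDL	ever smoking	CRYGN	prioritized	1	Colon Sigmoid,Nerve Tibial	FALSE	FALSE	FALSE
AA	LDL	ever smoking	FRK	prioritized	1	Muscle Skeletal	FALSE	FALSE	FALSE
AA	LDL	ever smoking	WDR86	prioritized	1	Nerve Tibial	FALSE	FALSE	FALSE
AA	TG	current drinking	BAHD1	prioritized	2	Colon Sigmoid,Stomach,Thyroid	TRUE	FALSE	FALSE
AA	TG	current drinking	DNAJC17	prioritized	2	Esophagus Mucosa	FALSE	FALSE	FALSE
AA	TG	ever smoking	TRIO	prioritized	1	Ovary	FALSE	FALSE	FALSE
AA	DBP	ever smoking	FNTB	prioritized	3	Muscle Skeletal,Skin Sun Exposed Lower leg	FALSE	FALSE	FALSE
AA	DBP	ever smoking	RAB15	prioritized	3	Adipose Subcutaneous,Nerve Tibial,Thyroid	TRUE	FALSE	FALSE
AA	MAP	current smoking	CRTAC1	prioritized	1	Adipose Visceral Omentum,Artery Tibial	FALSE	FALSE	FALSE
AA	MAP	current smoking	SULT4A1	prioritized	1	Colon Sigmoid	FALSE	FALSE	FALSE
AA	MAP	ever smoking	FNTB	prioritized	3	Muscle Skeletal,Skin Sun Exposed Lower leg	FALSE	FALSE	FALSE
AA	MAP	ever smoking	RAB15	prioritized	3	Adipose Subcutaneous,Nerve Tibial,Thyroid	TRUE	FALSE	FALSE
AA	MAP	ever smoking	KCNK13	prioritized	1	Brain Hypothalamus	FALSE	FALSE	FALSE
AA	PP	current drinking	MPI	prioritized	4	Artery Aorta,Lung,Whole Blood	TRUE	FALSE	FALSE
AA	PP	current drinking	SCAMP2	prioritized	4	Esophagus Mucosa,Pituitary,Whole Blood	TRUE	FALSE	FALSE
AA	PP	current smoking	SYN2	further_prioritized	1	Artery Aorta	FALSE	TRUE	FALSE
AA	PP	ever smoking	JMJD4	prioritized	2	Nerve Tibial	FALSE	FALSE	FALSE
AA	SBP	current smoking	CRTAC1	prioritized	1	Adipose Visceral Omentum,Artery Tibial	FALSE	FALSE	FALSE
AA	SBP	ever smoking	FNTB	prioritized	2	Muscle Skeletal,Skin Sun Exposed Lower leg	FALSE	FALSE	FALSE
AA	SBP	ever smoking	RAB15	prioritized	2	Adipose Subcutaneous,Nerve Tibial,Thyroid	TRUE	FALSE	FALSE
AA	SBP	ever smoking	JMJD4	prioritized	1	Nerve Tibial	FALSE	FALSE	FALSE
ASA	HDL	ever smoking	KCTD10	prioritized	1	Artery Tibial,Skin Sun Exposed Lower leg	FALSE	FALSE	TRUE
ASA	HDL	ever smoking	MYO1H	prioritized	1	Lung	FALSE	FALSE	TRUE
ASA	HDL	ever smoking	UBE3B	prioritized	1	Colon Transverse,Skin Sun Exposed Lower leg	FALSE	FALSE	TRUE
ASA	LDL	drinking habits	CPNE2	prioritized	3	Cells Transformed fibroblasts	FALSE	FALSE	FALSE
ASA	LDL	ever smoking	KANK2	prioritized	2	Adipose Subcutaneous,Lung,Thyroid	TRUE	FALSE	TRUE
ASA	TG	drinking habits	LIPC	prioritized	1	Thyroid	FALSE	FALSE	TRUE
ASA	MAP	ever smoking	ALDH2	further_prioritized	2	Esophagus Mucosa,Lung,Nerve Tibial,Thyroid	TRUE	TRUE	TRUE
ASA	MAP	ever smoking	TMEM116	further_prioritized	1	Artery Tibial,Heart Atrial Appendage,Whole Blood	TRUE	TRUE	TRUE
ASA	SBP	current smoking	ALDH2	further_prioritized	3	Esophagus Mucosa,Brain Cortex,Thyroid	TRUE	TRUE	TRUE
ASA	SBP	ever smoking	ALDH2	further_prioritized	1	Esophagus Mucosa,Skin Sun Exposed Lower leg	FALSE	TRUE	TRUE
EA	LDL	drinking habits	APOC1	prioritized	1	Esophagus Mucosa	FALSE	FALSE	TRUE
EA	TG	drinking habits	KRTCAP3	prioritized	2	Adrenal Gland,Thyroid,Whole Blood	TRUE	FALSE	TRUE
EA	TG	drinking habits	PPM1G	prioritized	2	Adipose Subcutaneous,Stomach,Thyroid	TRUE	FALSE	TRUE
HA	PP	current smoking	STIM1	prioritized	2	Lung,Thyroid,Whole Blood	FALSE	FALSE	FALSE
TRANS	LDL	ever smoking	CRYGN	prioritized	1	Colon Sigmoid,Nerve Tibial	FALSE	FALSE	FALSE
TRANS	LDL	ever smoking	WDR86	prioritized	1	Nerve Tibial	FALSE	FALSE	FALSE
TRANS	TG	drinking habits	KRTCAP3	prioritized	1	Adrenal Gland,Thyroid,Whole Blood	TRUE	FALSE	TRUE
TRANS	TG	drinking habits	PPM1G	prioritized	1	Esophagus Muscularis,Muscle Skeletal	FALSE	FALSE	TRUE
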