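accession	gene_symbol	qc_violation_label	planted_regulated	archetype	l2fc_d3_d1	l2fc_d7_d1
PROT00001	GENE00001	none	FALSE	NA	0	0
PROT00002	GENE00002	none	FALSE	NA	0	0
PROT00003	GENE00003	none	FALSE	NA	0	0
PROT00004	GENE00004	none	FALSE	NA	0	0
PROT00005	GENE00005	high_variability	FALSE	NA	0	0
PROT00006	GENE00006	high_variability	FALSE	NA	0	0
PROT00007	GENE00007	none	FALSE	NA	0	0
PROT00008	GENE00008	none	FALSE	NA	0	0
PROT00009	GENE00009	none	FALSE	NA	0	0
PROT00010	GENE00010	none	TRUE	6	-0.9	-1
PROT00011	GENE00011	replicate_discordant	FALSE	NA	0	0
PROT00012	GENE00012	none	FALSE	NA	0	0
PROT00013	GENE00013	none	TRUE	2	0.1	1.2
PROT00014	GENE00014	none	TRUE	1	0.2	0.5
PROT00015	GENE00015	none	TRUE	1	0.2	0.5
PROT00016	GENE00016	none	FALSE	NA	0	0
PROT00017	GENE00017	none	FALSE	NA	0	0
PROT00018	GENE00018	none	FALSE	NA	0	0
PROT00019	GENE00019	none	TRUE	4	-0.2	-0.5
PROT00020	GENE00020	none	FALSE	NA	0	0
PROT00021	GENE00021	none	TRUE	2	0.1	1.2
PROT00022	GENE00022	none	FALSE	NA	0	0
PROT00023	GENE00023	none	FALSE	NA	0	0
PROT00024	GENE00024	none	TRUE	5	-0.1	-1.2
PROT00025	GENE00025	none	FALSE	NA	0	0
PROT00026	GENE00026	none	TRUE	1	0.2	0.5
PROT00027	GENE00027	few_peptides	FALSE	NA	0	0
PROT00028	GENE00028	none	FALSE	NA	0	0
PROT00029	GENE00029	few_peptides	FALSE	NA	0	0
PROT00030	GENE00030	none	TRUE	5	-0.1	-1.2
PROT00031	GENE00031	none	FALSE	NA	0	0
PROT00032	GENE00032	none	FALSE	NA	0	0
CON_KRT001	KRT1	contaminant	FALSE	NA	0	0
PROT00034	GENE00034	none	FALSE	NA	0	0
PROT00035	GENE00035	none	TRUE	6	-0.9	-1
PROT00036	GENE00036	none	FALSE	NA	0	0
CON_KRT002	KRT2	contaminant	FALSE	NA	0	0
PROT00038	GENE00038	none	TRUE	1	0.2	0.5
PROT00039	GENE00039	none	TRUE	2	0.1	1.2
PROT00040	GENE00040	high_variability	FALSE	NA	0	0
PROT00041	GENE00041	none	FALSE	NA	0	0
PROT00042	GENE00042	none	TRUE	4	-0.2	-0.5
PROT00043	GENE00043	none	FALSE	NA	0	0
PROT00044	GENE00044	none	TRUE	3	0.9	1
PROT00045	GENE00045	none	FALSE	NA	0	0
PROT00046	GENE00046	none	TRUE	3	0.9	1
PROT00047	GENE00047	none	TRUE	6	-0.9	-1
PROT00048	GENE00048	replicate_discordant	FALSE	NA	0	0
PROT00049	GENE00049	none	FALSE	NA	0	0
PROT00050	GENE00050	none	TRUE	3	0.9	1
PROT00051	GENE00051	none	FALSE	NA	0	0
PROT00052	GENE00052	replicate_discordant	FALSE	NA	0	0
PROT00053	GENE00053	few_peptides	FALSE	NA	0	0
PROT00054	GENE00054	none	TRUE	5	-0.1	-1.2
PROT00055	GENE00055	none	FALSE	NA	0	0
PROT00056	GENE00056	none	FALSE	NA	0	0
CON_KRT003	KRT3	contaminant	FALSE	NA	0	0
PROT00058	GENE00058	none	FALSE	NA	0	0
PROT00059	GENE00059	none	FALSE	NA	0	0
PROT00060	GENE00060	none	TRUE	4	-0.2	-0.5
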