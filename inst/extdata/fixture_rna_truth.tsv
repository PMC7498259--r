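gene_id	is_de	direction	l2fc_d3_d1	l2fc_d7_d1	l2fc_d7_d3
GENE00001	FALSE	none	0	0	0
GENE00002	TRUE	up	0.5528519670479	2	1.4471480329521
GENE00003	FALSE	none	0	0	0
GENE00004	FALSE	none	0	0	0
GENE00005	TRUE	down	-1.36190652661026	-2	-0.638093473389745
GENE00006	FALSE	none	0	0	0
GENE00007	FALSE	none	0	0	0
GENE00008	FALSE	none	0	0	0
GENE00009	FALSE	none	0	0	0
GENE00010	FALSE	none	0	0	0
GENE00011	FALSE	none	0	0	0
GENE00012	TRUE	up	1.08558182464913	2	0.914418175350875
GENE00013	FALSE	none	0	0	0
GENE00014	FALSE	none	0	0	0
GENE00015	FALSE	none	0	0	0
GENE00016	FALSE	none	0	0	0
GENE00017	FALSE	none	0	0	0
GENE00018	TRUE	down	-1.34152463381179	-2	-0.658475366188213
GENE00019	FALSE	none	0	0	0
GENE00020	TRUE	up	0.776101881172508	2	1.22389811882749
GENE00021	TRUE	down	-0.51466558361426	-2	-1.48533441638574
GENE00022	FALSE	none	0	0	0
GENE00023	FALSE	none	0	0	0
GENE00024	FALSE	none	0	0	0
GENE00025	FALSE	none	0	0	0
GENE00026	TRUE	down	-0.749641687143594	-2	-1.25035831285641
GENE00027	FALSE	none	0	0	0
GENE00028	FALSE	none	0	0	0
GENE00029	FALSE	none	0	0	0
GENE00030	FALSE	none	0	0	0
GENE00031	FALSE	none	0	0	0
GENE00032	FALSE	none	0	0	0
GENE00033	FALSE	none	0	0	0
GENE00034	TRUE	up	1.03892848244868	2	0.961071517551318
GENE00035	FALSE	none	0	0	0
GENE00036	FALSE	none	0	0	0
GENE00037	FALSE	none	0	0	0
GENE00038	FALSE	none	0	0	0
GENE00039	FALSE	none	0	0	0
GENE00040	FALSE	none	0	0	0
GENE00041	FALSE	none	0	0	0
GENE00042	FALSE	none	0	0	0
GENE00043	FALSE	none	0	0	0
GENE00044	FALSE	none	0	0	0
GENE00045	FALSE	none	0	0	0
GENE00046	FALSE	none	0	0	0
GENE00047	TRUE	up	0.768816440599039	2	1.23118355940096
GENE00048	FALSE	none	0	0	0
GENE00049	FALSE	none	0	0	0
GENE00050	TRUE	down	-1.15537958894856	-2	-0.844620411051437
GENE00051	FALSE	none	0	0	0
GENE00052	FALSE	none	0	0	0
GENE00053	FALSE	none	0	0	0
GENE00054	FALSE	none	0	0	0
GENE00055	FALSE	none	0	0	0
GENE00056	FALSE	none	0	0	0
GENE00057	FALSE	none	0	0	0
GENE00058	FALSE	none	0	0	0
GENE00059	FALSE	none	0	0	0
GENE00060	FALSE	none	0	0	0
GENE00061	FALSE	none	0	0	0
GENE00062	TRUE	down	-1.28004684508778	-2	-0.719953154912218
GENE00063	TRUE	up	0.848152222111821	2	1.15184777788818
GENE00064	FALSE	none	0	0	0
GENE00065	TRUE	up	1.31435111770406	2	0.685648882295936
GENE00066	FALSE	none	0	0	0
GENE00067	FALSE	none	0	0	0
GENE00068	FALSE	none	0	0	0
GENE00069	FALSE	none	0	0	0
GENE00070	FALSE	none	0	0	0
GENE00071	TRUE	up	1.23410336649977	2	0.765896633500233
GENE00072	FALSE	none	0	0	0
GENE00073	FALSE	none	0	0	0
GENE00074	FALSE	none	0	0	0
GENE00075	FALSE	none	0	0	0
GENE00076	FALSE	none	0	0	0
GENE00077	FALSE	none	0	0	0
GENE00078	FALSE	none	0	0	0
GENE00079	FALSE	none	0	0	0
GENE00080	FALSE	none	0	0	0
GENE00081	FALSE	none	0	0	0
GENE00082	FALSE	none	0	0	0
GENE00083	FALSE	none	0	0	0
GENE00084	TRUE	down	-1.42949969228357	-2	-0.570500307716429
GENE00085	TRUE	up	0.985107853310183	2	1.01489214668982
GENE00086	FALSE	none	0	0	0
GENE00087	FALSE	none	0	0	0
GENE00088	FALSE	none	0	0	0
GENE00089	FALSE	none	0	0	0
GENE00090	FALSE	none	0	0	0
GENE00091	FALSE	none	0	0	0
GENE00092	FALSE	none	0	0	0
GENE00093	FALSE	none	0	0	0
GENE00094	FALSE	none	0	0	0
GENE00095	FALSE	none	0	0	0
GENE00096	FALSE	none	0	0	0
GENE00097	TRUE	up	1.18905465397984	2	0.810945346020162
GENE00098	FALSE	none	0	0	0
GENE00099	FALSE	none	0	0	0
GENE00100	TRUE	up	1.36916280328296	2	0.630837196717039
GENE00101	TRUE	down	-1.43105852254666	-2	-0.568941477453336
GENE00102	FALSE	none	0	0	0
GENE00103	TRUE	down	-0.580190767534077	-2	-1.41980923246592
GENE00104	FALSE	none	0	0	0
GENE00105	FALSE	none	0	0	0
GENE00106	FALSE	none	0	0	0
GENE00107	FALSE	none	0	0	0
GENE00108	FALSE	none	0	0	0
GENE00109	TRUE	up	1.32917335163802	2	0.670826648361981
GENE00110	FALSE	none	0	0	0
GENE00111	FALSE	none	0	0	0
GENE00112	FALSE	none	0	0	0
GENE00113	FALSE	none	0	0	0
GENE00114	FALSE	none	0	0	0
GENE00115	FALSE	none	0	0	0
GENE00116	FALSE	none	0	0	0
GENE00117	FALSE	none	0	0	0
GENE00118	FALSE	none	0	0	0
GENE00119	FALSE	none	0	0	0
GENE00120	TRUE	down	-0.869002459105104	-2	-1.1309975408949
GENE00121	FALSE	none	0	0	0
GENE00122	FALSE	none	0	0	0
GENE00123	FALSE	none	0	0	0
GENE00124	FALSE	none	0	0	0
GENE00125	FALSE	none	0	0	0
GENE00126	FALSE	none	0	0	0
GENE00127	FALSE	none	0	0	0
GENE00128	TRUE	up	0.524913101922721	2	1.47508689807728
GENE00129	TRUE	down	-0.697572726989165	-2	-1.30242727301084
GENE00130	FALSE	none	0	0	0
GENE00131	FALSE	none	0	0	0
GENE00132	FALSE	none	0	0	0
GENE00133	FALSE	none	0	0	0
GENE00134	FALSE	none	0	0	0
GENE00135	TRUE	down	-1.1977859493345	-2	-0.802214050665498
GENE00136	FALSE	none	0	0	0
GENE00137	FALSE	none	0	0	0
GENE00138	FALSE	none	0	0	0
GENE00139	FALSE	none	0	0	0
GENE00140	FALSE	none	0	0	0
GENE00141	FALSE	none	0	0	0
GENE00142	FALSE	none	0	0	0
GENE00143	FALSE	none	0	0	0
GENE00144	FALSE	none	0	0	0
GENE00145	FALSE	none	0	0	0
GENE00146	FALSE	none	0	0	0
GENE00147	FALSE	none	0	0	0
GENE00148	FALSE	none	0	0	0
GENE00149	FALSE	none	0	0	0
GENE00150	FALSE	none	0	0	0
GENE00151	FALSE	none	0	0	0
GENE00152	FALSE	none	0	0	0
GENE00153	FALSE	none	0	0	0
GENE00154	FALSE	none	0	0	0
GENE00155	FALSE	none	0	0	0
GENE00156	FALSE	none	0	0	0
GENE00157	FALSE	none	0	0	0
GENE00158	FALSE	none	0	0	0
GENE00159	FALSE	none	0	0	0
GENE00160	TRUE	down	-1.44238174962811	-2	-0.557618250371888
GENE00161	FALSE	none	0	0	0
GENE00162	FALSE	none	0	0	0
GENE00163	FALSE	none	0	0	0
GENE00164	FALSE	none	0	0	0
GENE00165	FALSE	none	0	0	0
GENE00166	FALSE	none	0	0	0
GENE00167	FALSE	none	0	0	0
GENE00168	TRUE	down	-1.24720211955719	-2	-0.752797880442813
GENE00169	FALSE	none	0	0	0
GENE00170	FALSE	none	0	0	0
GENE00171	FALSE	none	0	0	0
GENE00172	TRUE	up	0.794349320000038	2	1.20565067999996
GENE00173	FALSE	none	0	0	0
GENE00174	FALSE	none	0	0	0
GENE00175	FALSE	none	0	0	0
GENE00176	FALSE	none	0	0	0
GENE00177	FALSE	none	0	0	0
GENE00178	FALSE	none	0	0	0
GENE00179	TRUE	up	0.54280965635553	2	1.45719034364447
GENE00180	FALSE	none	0	0	0
GENE00181	FALSE	none	0	0	0
GENE00182	FALSE	none	0	0	0
GENE00183	FALSE	none	0	0	0
GENE00184	FALSE	none	0	0	0
GENE00185	FALSE	none	0	0	0
GENE00186	FALSE	none	0	0	0
GENE00187	FALSE	none	0	0	0
GENE00188	FALSE	none	0	0	0
GENE00189	FALSE	none	0	0	0
GENE00190	FALSE	none	0	0	0
GENE00191	FALSE	none	0	0	0
GENE00192	FALSE	none	0	0	0
GENE00193	FALSE	none	0	0	0
GENE00194	FALSE	none	0	0	0
GENE00195	FALSE	none	0	0	0
GENE00196	TRUE	down	-1.20691174222156	-2	-0.793088257778436
GENE00197	FALSE	none	0	0	0
GENE00198	FALSE	none	0	0	0
GENE00199	FALSE	none	0	0	0
GENE00200	FALSE	none	0	0	0
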