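term_id	category	planted_enriched
GO:0000001	MF	TRUE
GO:0000002	CC	TRUE
GO:0000003	MF	TRUE
GO:0000004	MF	FALSE
GO:0000005	MF	FALSE
GO:0000006	CC	FALSE
GO:0000007	MF	FALSE
GO:0000008	CC	FALSE
GO:0000009	MF	FALSE
GO:0000010	CC	FALSE
GO:0000011	CC	FALSE
GO:0000012	BP	FALSE
GO:0000013	CC	FALSE
GO:0000014	BP	FALSE
GO:0000015	CC	FALSE
GO:0000016	BP	FALSE
GO:0000017	BP	FALSE
GO:0000018	MF	FALSE
GO:0000019	CC	FALSE
GO:0000020	CC	FALSE
GO:0000021	MF	FALSE
GO:0000022	MF	FALSE
GO:0000023	MF	FALSE
GO:0000024	MF	FALSE
GO:0000025	MF	FALSE
GO:0000026	CC	FALSE
GO:0000027	BP	FALSE
GO:0000028	BP	FALSE
GO:0000029	BP	FALSE
GO:0000030	MF	FALSE
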