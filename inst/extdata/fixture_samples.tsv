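sample_id	timepoint	bio_rep	tech_rep
day1_A1	day1	A	1
day1_A2	day1	A	2
day1_B1	day1	B	1
day1_B2	day1	B	2
day3_A1	day3	A	1
day3_A2	day3	A	2
day3_B1	day3	B	1
day3_B2	day3	B	2
day7_A1	day7	A	1
day7_A2	day7	A	2
day7_B1	day7	B	1
day7_B2	day7	B	2
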