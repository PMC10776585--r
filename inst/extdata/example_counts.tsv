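variant_id	chrom	pos	ref	alt	v_f	a_f	v_m	a_m	hom_f	hemi_m
rs201580891	X	147912050	G	T	18736	104056	0	38527	0	0
parvar_1	X	500000	A	G	50	2000	30	1100	1	30
parvar_2	X	1000000	C	T	500	2000	150	1000	60	150
xvar_1	X	74000000	T	C	10	10000	6	5000	0	6
auto_1	21	5030000	G	A	40	9000	25	5200	0	0
auto_2	21	6100000	C	G	4	9000	0	5200	0	0
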