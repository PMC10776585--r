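variant_id	gene	clinvar_class	qc_fail_genomes	omim_link	structural_prediction
rs201580891	FMR1	LIKELY_BENIGN	yes	SPECIFIC	NEUTRAL
rs1315062158	IQSEC	BENIGN_OR_LIKELY_BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs782666190	SMC1A	BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs1432363549	SMC1A	LIKELY_BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs782705493	HDAC8	BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs777010333	COL4A6	LIKELY_BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs782664878	SMC1A	BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs372580592	SLC9A6	LIKELY_BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs782792601	NDUFB11	BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs782032695	EBP	LIKELY_BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs781824575	HDAC8	BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs745354475	USP9X	BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs199626569	GJB1	UNCERTAIN	not_assessed	SPECIFIC	NEUTRAL
rs782072345	NDUFB11	BENIGN	no	SPECIFIC	NOT_APPLICABLE
rs745338783	POLA1	LIKELY_BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs751314374	RPGR	CONFLICTING	yes	SPECIFIC	NEUTRAL
rs1250133030	RPGR	LIKELY_BENIGN	yes	SPECIFIC	UNCLEAR
rs72609545	VCX3A	BENIGN	yes	TENTATIVE	NEUTRAL
rs12849277	MED12	BENIGN_OR_LIKELY_BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs781379769	USP9X	BENIGN_OR_LIKELY_BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs145404090	SAGE1	UNCERTAIN	yes	TENTATIVE	NEUTRAL
rs148934011	RBMX	UNCERTAIN	yes	SPECIFIC	STABILIZING
rs782233695	RHOXF2	LIKELY_BENIGN	yes	NONE	UNCLEAR
rs1446705794	RPGR	LIKELY_BENIGN	yes	SPECIFIC	NOT_APPLICABLE
rs201558029	DMD	BENIGN	no	SPECIFIC	NOT_APPLICABLE
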