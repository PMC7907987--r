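entry_id	gene	alt_pattern	context	evidence	germline_risk	germline_therapeutic
KB001	EGFR	mutation	lung	FDA_APPROVED_BENEFIT	NONE	FALSE
KB002	ERBB2	amplification	breast	FDA_APPROVED_BENEFIT	NONE	FALSE
KB003	BRAF	mutation	melanoma	FDA_APPROVED_BENEFIT	NONE	FALSE
KB004	ALK	fusion	lung	FDA_APPROVED_BENEFIT	NONE	FALSE
KB005	KRAS	mutation	lung	FDA_APPROVED_RESISTANCE	NONE	FALSE
KB006	ERBB2	amplification	ANY	INVESTIGATIONAL_OR_OFF_LABEL	NONE	FALSE
KB007	CDK4	amplification	ANY	INVESTIGATIONAL_OR_OFF_LABEL	NONE	FALSE
KB008	FGFR2	fusion	ANY	INVESTIGATIONAL_OR_OFF_LABEL	NONE	FALSE
KB009	PIK3CA	mutation	ANY	INVESTIGATIONAL_OR_OFF_LABEL	NONE	FALSE
KB010	PTEN	homozygous_deletion	ANY	INVESTIGATIONAL_OR_OFF_LABEL	NONE	FALSE
KB011	MDM2	amplification	ANY	PRECLINICAL_RESISTANCE	NONE	FALSE
KB012	NRAS	mutation	ANY	PRECLINICAL_RESISTANCE	NONE	FALSE
KB013	TP53	mutation	ANY	BIOLOGICAL_ONLY	NONE	FALSE
KB014	MYC	amplification	ANY	BIOLOGICAL_ONLY	NONE	FALSE
KB015	CDKN2A	homozygous_deletion	ANY	BIOLOGICAL_ONLY	NONE	FALSE
KB016	ARID1A	mutation	ANY	BIOLOGICAL_ONLY	NONE	FALSE
KB017	HPV16	viral	ANY	BIOLOGICAL_ONLY	NONE	FALSE
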