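partner	dctpr	evidence
Tom20	Tom70	dc_clamp_prior
Tom20	AIP	dc_clamp_prior
Rpn13	SGTA	dc_clamp_prior
Usp19	AIP	dc_clamp_this_study
Usp19	FKBP51	dc_clamp_this_study
Hsp105	AIP	dc_clamp_this_study
Hsp105	FKBP51	dc_clamp_this_study
DNAAF2	AIP	dc_clamp_this_study
DNAAF2	FKBP51	dc_clamp_this_study
NADSYN1	AIP	dc_clamp_this_study
NADSYN1	FKBP51	dc_clamp_this_study
Usp19	DNAJC7	interaction_database
Usp19	FKBP52	interaction_database
Usp19	FKBP36	interaction_database
Usp19	FKBP38	interaction_database
Usp19	FKBPL	interaction_database
Usp19	CHIP	interaction_database
Usp19	UNC45A	interaction_database
p23	Tom70	chaperone_interactome
Hsp90b	FKBP51	dc_clamp_prior
Hsp70.1	FKBP51	dc_clamp_prior
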