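status	drug	pathway	steps	joint_p
approved	Vemurafenib	BRAF	2	0.98
phase_iii	Dabrafenib	BRAF	2	0.98
phase_iii	Sorafenib	BRAF	2	0.98
phase_iii	Vinblastine	MAP kinase	3	0.93
phase_ii	Zidovudine	TERT	2	0.98
phase_ii	Trametinib	MAP kinase	2	0.98
phase_ii	Regorafenib	BRAF	2	0.98
phase_ii	Nadroparin	MYC	3	0.97
phase_ii	Vinorelbine	MAP kinase	3	0.93
phase_ii	Irinotecan	CDKN2A	3	0.93
phase_ii	Topotecan	CDKN2A	3	0.93
phase_i	Sodium stibogluconate	CDKN2A	3	0.93
case_study	Ingenol mebutate	PRKCA/BRAF	3	0.95
in_vitro	Bosutinib	MAP kinase	2	0.98
in_vitro	Purvalanol	MAP kinase/TP53	3	0.97
in_vitro	Ellagic acid	PRKCA/BRAF	3	0.95
in_vitro	Albendazole	CDKN2A	3	0.93
in_vitro	Colchicine	MAP kinase	3	0.93
in_vivo	Plerixafor	CXCR4	3	0.97
in_vivo	Vincristine	MAP kinase	3	0.93
in_vivo	L-Methionine	CDKN2A	3	0.93
in_vivo	Mebendazole	CDKN2A	3	0.93
novel	Framycetin	CXCR4	3	0.97
novel	Lucanthone	CDKN2A	3	0.93
novel	Podofilox	MAP kinase	3	0.93
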