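# Reference results of a three-tissue cannabis-extract inflammation screen
# (EpiDermFT skin irradiated with UVC; EpiOral and EpiIntestinal tissues
# exposed to TNFa), as printed at reporting precision: t and CDEI to 2
# decimals, p to 2 significant figures. Each dataset's t statistic is a
# one-sample t of the weighted per-pathway SPIA means over 241 pathways
# (df = 240). Used by tests and by scripts/acceptance.R as printed inputs
# to the CDEI formula layer. The EpiDermFT untreated p-value (0.23) is a
# known typographical error in the source report (2-sided p at t = 1.04,
# df = 240 is 0.30) and is excluded from t-to-p checks.
experiment	dataset	sample_class	n_profiles	t_value	p_value	cdei
EpiDermFT	DMSO	control	3	0	1	NA
EpiDermFT	UV	untreated	3	1.04	0.23	0.00
EpiDermFT	Extract #4	treated	5	0.67	0.50	0.22
EpiDermFT	Extract #12	treated	5	2.06	0.04	-0.33
EpiDermFT	Extract #8	treated	5	-0.19	0.85	0.69
EpiDermFT	Extract #13	treated	5	-1.04	0.30	0.00
EpiOral	DMSO	control	NA	NA	NA	NA
EpiOral	TNFa	untreated	NA	-2.78	0.006	0.00
EpiOral	Extract #1	treated	NA	0.86	0.39	0.53
EpiOral	Extract #7	treated	NA	0.19	0.85	0.87
EpiOral	Extract #9	treated	NA	-0.03	0.98	0.98
EpiOral	Extract #45	treated	NA	-2.02	0.04	0.16
EpiOral	Extract #115	treated	NA	-0.15	0.88	0.90
EpiOral	Extract #129	treated	NA	-0.63	0.53	0.63
EpiOral	Extract #157	treated	NA	-0.29	0.77	0.81
EpiOral	Extract #167	treated	NA	-2.27	0.02	0.10
EpiOral	Extract #169	treated	NA	-0.17	0.86	0.88
EpiIntestinal	DMSO	control	NA	NA	NA	NA
EpiIntestinal	TNFa	untreated	NA	2.43	0.016	0.00
EpiIntestinal	Extract #1	treated	NA	-1.37	0.17	0.28
EpiIntestinal	Extract #7	treated	NA	1.15	0.25	0.36
EpiIntestinal	Extract #9	treated	NA	1.43	0.15	0.26
EpiIntestinal	Extract #45	treated	NA	1.02	0.31	0.41
EpiIntestinal	Extract #115	treated	NA	0.21	0.84	0.84
EpiIntestinal	Extract #129	treated	NA	-0.56	0.58	0.63
EpiIntestinal	Extract #130	treated	NA	1.56	0.12	0.22
EpiIntestinal	Extract #169	treated	NA	1.75	0.08	0.16
EpiIntestinal	Extract #274	treated	NA	0.99	0.32	0.42
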