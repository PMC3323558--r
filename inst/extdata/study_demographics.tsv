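# Demographic characteristics of the genotyped affected subjects of a
# familial-longevity study: counts by attained-age band and sex, for all
# affected individuals and for the subset with a genotyped affected
# relative (the subjects entering the linkage analysis).
age_band	affected_male	affected_female	typed_relative_male	typed_relative_female	typed_relative_total
86-89	36	5	27	5	32
90-92	65	60	51	49	100
93-95	65	53	50	41	91
96-97	43	21	31	16	47
98-99	19	18	7	13	20
100+	19	29	14	21	35
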