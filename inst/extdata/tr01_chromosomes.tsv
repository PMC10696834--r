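# Printed chromosome table of the study dikaryon: per-haplotype sizes at
# Mb precision, gene counts, centromere presence and telomere state.
# Centromere positions are NOT printed; models built from this table use a
# synthetic mid-chromosome placement. The extra chromosome of haplotype B
# (Chr12B) is centromere-free.
chrom	haplotype	length_bp	genes	has_centromere	telomere_5p	telomere_3p
Chr01A	A	8650000	2838	TRUE	TRUE	TRUE
Chr02A	A	3630000	1097	TRUE	TRUE	TRUE
Chr03A	A	2670000	823	TRUE	TRUE	TRUE
Chr04A	A	2490000	683	TRUE	TRUE	TRUE
Chr05A	A	2360000	713	TRUE	TRUE	TRUE
Chr06A	A	2300000	678	TRUE	TRUE	TRUE
Chr07A	A	2330000	729	TRUE	TRUE	TRUE
Chr08A	A	1580000	509	TRUE	TRUE	TRUE
Chr09A	A	860000	142	TRUE	TRUE	TRUE
Chr10A	A	830000	188	TRUE	TRUE	TRUE
Chr11A	A	430000	80	TRUE	TRUE	TRUE
Chr01B	B	6590000	2132	TRUE	TRUE	TRUE
Chr02B	B	2500000	767	TRUE	TRUE	TRUE
Chr03B	B	2640000	833	TRUE	TRUE	TRUE
Chr04B	B	2410000	676	TRUE	TRUE	TRUE
Chr05B	B	4560000	1372	TRUE	TRUE	TRUE
Chr06B	B	2320000	689	TRUE	TRUE	TRUE
Chr07B	B	2210000	712	TRUE	TRUE	TRUE
Chr08B	B	1520000	495	TRUE	TRUE	TRUE
Chr09B	B	850000	142	TRUE	TRUE	TRUE
Chr10B	B	810000	186	TRUE	TRUE	TRUE
Chr11B	B	420000	76	TRUE	TRUE	TRUE
Chr12B	B	1510000	483	FALSE	TRUE	TRUE
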