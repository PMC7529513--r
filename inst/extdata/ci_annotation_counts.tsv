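annotation	top_ci_n	ext_ci_n
intergenic	6642	12421
upstream	764	965
downstream	773	1039
3_prime_utr	41	50
5_prime_utr	14	14
intronic	3286	6077
synonymous	105	133
non_coding_transcript_exon	4	6
splicing_region	17	27
missense	50	66
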