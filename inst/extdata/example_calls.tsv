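sample_id	arm	allele	tl_p75_bp	tvr_len_bp	n_supporting_reads	mapping_ambiguous
S00001	1p	1	4512	310	6	FALSE
S00001	1p	2	5230	180	4	FALSE
S00001	7q	1	3894	95	5	FALSE
S00002	7q	1	2987	-12	7	FALSE
S00002	17p	1	2411	40	3	TRUE
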