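sequence	annotation	s1	s2
GCATTGGTGGTTCAGTGGTAGAATTCTCGC	tRNA-Gly-GCC:1-30	30	20
GCATTGGTGGTTCAGTGGTAGAATTCTCGCC	tRNA-Gly-GCC:1-31	10	10
GCATTGGTGGTTCAGTGGTAGAATT	tRNA-Gly-GCC;tRNA-Gly-CCC	8	6
GCGCCGCTGGTGTAGTGGTATCATGCA	tRNA-Gly-CCC	5	5
CGCGACCTCAGATCAGACGTGGCGA	28S	1	1
CGCGACCTCAGATCAGACGTGG	28S	4	2
GGCTGGTCCGAAGGTAGTGAGTTATCTCA	RNY1	0	0
TTTGGCATTCAAGCAACTGTTCAA	some_unknown_parent	9	9
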