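sample_id	chrom	pos	ref	alt	var_type	genotype	qual_a	qual_b	consequence	gene	freq_esp	freq_hapmap	score
BRCA1.60	1	1126808	C	T	snv	het	200	200	splice_disrupt	CHEK2			
BRCA1.61	3	1060784	CA	C	del	het	250	250	frameshift	ATM			
BRCA2.7	11	1113708	C	T	snv	het	200	200	misstart	RAD50			
BRCA2.13	3	1060794	C	T	snv	het	200	200	nonsense	ATM			
BRCA2.65	1	1181566	C	T	snv	het	200	200	nonsense	CDKN2B			
BRCA2.93	1	1126818	C	T	snv	het	200	200	nonsense	CHEK2			
BRCA1.48	12	1125367	C	T	snv	het	200	200	nonsense	ERCC3			
BRCA1.73	17	1123140	C	T	snv	het	200	200	splice_disrupt	DLEC1			
BRCA1.74	4	1135847	C	T	snv	het	200	200	nonsense	FANCC			
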