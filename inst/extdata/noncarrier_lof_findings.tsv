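sample_id	chrom	pos	ref	alt	var_type	genotype	qual_a	qual_b	consequence	gene	freq_esp	freq_hapmap	score
UTSW3	14	1079517	C	T	snv	het	200	200	nonsense	TP53			
UTSW12	9	1055806	CA	C	del	het	250	250	frameshift	APC			
UTSW13	17	1028034	CA	C	del	het	250	250	frameshift	FH			
UTSW16	9	1055816	CA	C	del	het	250	250	frameshift	APC			
UTSW31	16	1088425	CA	C	del	het	250	250	frameshift	MSH6			
UTSW32	16	1088445	C	T	snv	het	200	200	nonsense	MSH6			
UTSW38	17	1028034	CA	C	del	het	250	250	frameshift	FH			
UTSW44	22	1086329	C	T	snv	het	200	200	nonsense	MSH2			
UTSW53	16	1088455	CA	C	del	het	250	250	frameshift	MSH6			
UTSW55	9	1055826	CA	C	del	het	250	250	frameshift	APC			
UTSW78	3	1060804	CA	C	del	het	250	250	frameshift	ATM			
UTSW78	11	1113718	CA	C	del	het	250	250	frameshift	RAD50			
UTSW9	7	1124712	C	T	snv	het	200	200	nonsense	PALB2			
UTSW13	22	1167025	C	T	snv	het	200	200	nonsense	RAD51C			
UTSW36	7	1124722	C	T	snv	het	200	200	nonsense	PALB2			
UTSW22	10	1142397	C	T	snv	het	200	200	nonsense	FANCM			
UTSW51	10	1142397	C	T	snv	het	200	200	nonsense	FANCM			
UTSW76	12	1125367	C	T	snv	het	200	200	nonsense	ERCC3			
UTSW82	16	1134537	C	T	snv	het	200	200	nonsense	FANCA			
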