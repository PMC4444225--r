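gene	inheritance	cancer_associated	coding_length	excluded
ACTA2	dominant	FALSE	1319	FALSE
ACTC1	dominant	FALSE	2234	FALSE
ACVRL1	dominant	FALSE	2480	FALSE
APC	dominant	TRUE	842	FALSE
APOB	dominant	FALSE	1661	FALSE
ATM	dominant	TRUE	1337	FALSE
ATR	dominant	TRUE	1525	FALSE
BAP1	dominant	TRUE	2501	FALSE
BARD1	dominant	TRUE	2569	FALSE
BMPR1A	dominant	TRUE	2648	FALSE
BRCA1	dominant	TRUE	1407	FALSE
BRCA2	dominant	TRUE	1199	FALSE
BRIP1	dominant	TRUE	4999	FALSE
CACNA1C	dominant	FALSE	2946	FALSE
CACNA1S	dominant	FALSE	3601	FALSE
CACNB2	dominant	FALSE	885	FALSE
CDC73	dominant	TRUE	544	FALSE
CDH1	dominant	TRUE	663	FALSE
CDK4	dominant	TRUE	636	FALSE
CDKN1A	dominant	TRUE	2448	FALSE
CDKN2A	dominant	TRUE	6704	FALSE
CDKN2B	dominant	TRUE	704	FALSE
CHEK1	dominant	TRUE	4766	FALSE
CHEK2	dominant	TRUE	3825	FALSE
CNBP	dominant	FALSE	9316	FALSE
COL3A1	dominant	FALSE	3216	FALSE
CREBBP	dominant	TRUE	2822	FALSE
DMPK	dominant	FALSE	671	FALSE
DSC2	dominant	FALSE	2217	FALSE
DSG2	dominant	FALSE	2142	FALSE
DSP	dominant	FALSE	6964	FALSE
EGFR	dominant	TRUE	3172	FALSE
ELAC2	dominant	TRUE	2052	FALSE
ENG	dominant	FALSE	992	FALSE
EPCAM	dominant	TRUE	1111	FALSE
FAM175A	dominant	TRUE	2838	FALSE
FBN1	dominant	FALSE	3160	FALSE
FH	dominant	TRUE	1026	FALSE
FLCN	dominant	TRUE	1226	FALSE
GALNT12	dominant	TRUE	8654	FALSE
GCH1	dominant	FALSE	5144	FALSE
GEN1	dominant	TRUE	2957	TRUE
GPD1L	dominant	FALSE	1199	FALSE
GREM1	dominant	TRUE	853	FALSE
HCN4	dominant	FALSE	3733	FALSE
HIP1	dominant	FALSE	3654	FALSE
HIP1R	dominant	FALSE	1382	FALSE
HMBS	dominant	FALSE	488	FALSE
HOXB1	dominant	FALSE	834	FALSE
HOXB13	dominant	TRUE	3791	FALSE
HTT	dominant	FALSE	1034	FALSE
JAK2	dominant	TRUE	3439	FALSE
KCNE1	dominant	FALSE	2285	FALSE
KCNE2	dominant	FALSE	3141	FALSE
KCNE3	dominant	FALSE	2183	FALSE
KCNH1	dominant	FALSE	1030	FALSE
KCNH2	dominant	FALSE	484	FALSE
KCNJ2	dominant	FALSE	923	FALSE
KCNQ1	dominant	FALSE	613	FALSE
KDR	dominant	TRUE	2646	FALSE
KIT	dominant	TRUE	1499	FALSE
LDLR	dominant	FALSE	1758	FALSE
LMNA	dominant	FALSE	1980	FALSE
MEN1	dominant	TRUE	1781	FALSE
MET	dominant	TRUE	893	FALSE
MITF	dominant	TRUE	878	FALSE
MLH1	dominant	TRUE	1884	FALSE
MLH3	dominant	TRUE	5279	FALSE
MRE11A	dominant	TRUE	566	FALSE
MSH2	dominant	TRUE	12514	FALSE
MSH6	dominant	TRUE	2003	FALSE
MUTYH	dominant	TRUE	6841	FALSE
MYBPC3	dominant	FALSE	3259	FALSE
MYH11	dominant	FALSE	2735	FALSE
MYH7	dominant	FALSE	2329	FALSE
MYL2	dominant	FALSE	7962	FALSE
MYL3	dominant	FALSE	2863	FALSE
MYLK	dominant	FALSE	2551	FALSE
NBN	dominant	TRUE	2095	FALSE
NF1	dominant	TRUE	3468	FALSE
NF2	dominant	TRUE	1022	FALSE
NTRK1	dominant	TRUE	1308	FALSE
PALB2	dominant	TRUE	3355	FALSE
PCSK9	dominant	FALSE	3022	FALSE
PDGFRA	dominant	TRUE	1320	FALSE
PKP2	dominant	FALSE	3063	FALSE
PLN	dominant	FALSE	2588	FALSE
PMS2	dominant	TRUE	864	FALSE
PRKAG2	dominant	FALSE	1737	FALSE
PRKAR1A	dominant	FALSE	2624	FALSE
PROC	dominant	FALSE	545	FALSE
PROS1	dominant	FALSE	1027	FALSE
PRSS1	dominant	FALSE	548	FALSE
PTCH1	dominant	TRUE	2950	FALSE
PTEN	dominant	TRUE	1032	FALSE
RAD50	dominant	TRUE	659	FALSE
RAD51	dominant	TRUE	1697	FALSE
RAD51C	dominant	TRUE	936	FALSE
RAD51D	dominant	TRUE	1335	FALSE
RAS	dominant	TRUE	3992	FALSE
RB1	dominant	TRUE	728	FALSE
RBBP8	dominant	FALSE	1527	FALSE
RBM20	dominant	FALSE	5031	FALSE
RET	dominant	TRUE	2528	FALSE
RYR1	dominant	FALSE	2112	FALSE
RYR2	dominant	FALSE	1562	FALSE
SCN1B	dominant	FALSE	6154	FALSE
SCN3B	dominant	FALSE	1795	FALSE
SCN5A	dominant	FALSE	3199	FALSE
SDHAF2	dominant	TRUE	2460	FALSE
SDHB	dominant	TRUE	3066	FALSE
SDHC	dominant	TRUE	2078	FALSE
SDHD	dominant	TRUE	2299	FALSE
SERPINC1	dominant	FALSE	405	FALSE
SGCD	dominant	FALSE	4014	FALSE
SMAD3	dominant	FALSE	1227	FALSE
SMAD4	dominant	TRUE	1774	FALSE
SMARCB1	dominant	TRUE	2320	FALSE
SMO	dominant	TRUE	1116	FALSE
STK11	dominant	TRUE	3214	FALSE
TGFB3	dominant	FALSE	955	FALSE
TGFBR1	dominant	FALSE	3555	FALSE
TGFBR2	dominant	FALSE	3854	FALSE
TMEM43	dominant	FALSE	4732	FALSE
TNNI3	dominant	FALSE	4346	FALSE
TNNT2	dominant	FALSE	3610	FALSE
TP53	dominant	TRUE	2136	FALSE
TP53BP1	dominant	TRUE	1544	FALSE
TPM1	dominant	FALSE	656	FALSE
TSC1	dominant	TRUE	1727	FALSE
TSC2	dominant	TRUE	3307	FALSE
VHL	dominant	TRUE	4480	FALSE
WT1	dominant	TRUE	1454	FALSE
XRCC2	dominant	TRUE	1480	FALSE
XRCC3	dominant	TRUE	2224	FALSE
ATP7B	recessive	FALSE	1764	FALSE
BCHE	recessive	FALSE	1858	FALSE
BLM	recessive	TRUE	2423	FALSE
CASQ2	recessive	FALSE	5753	FALSE
CFTR	recessive	FALSE	1302	FALSE
COQ2	recessive	FALSE	7542	FALSE
COQ9	recessive	FALSE	3251	FALSE
CPT2	recessive	FALSE	1579	FALSE
F5	recessive	FALSE	2481	FALSE
GAA	recessive	FALSE	2042	FALSE
HAMP	recessive	FALSE	1606	FALSE
HFE	recessive	FALSE	566	FALSE
HFE2	recessive	FALSE	1110	FALSE
IDUA	recessive	FALSE	1105	FALSE
INPP5B	recessive	FALSE	622	FALSE
LDLRAP1	recessive	FALSE	1708	FALSE
PAH	recessive	FALSE	1300	FALSE
PCBD1	recessive	FALSE	856	FALSE
PTS	recessive	FALSE	7170	FALSE
QDPR	recessive	FALSE	1878	FALSE
SERPINA1	recessive	FALSE	988	FALSE
SLC25A13	recessive	FALSE	1617	FALSE
SLC37A4	recessive	FALSE	2935	FALSE
SLC7A9	recessive	FALSE	1405	FALSE
DMD	x_linked	FALSE	1090	FALSE
EMD	x_linked	FALSE	12794	FALSE
GLA	x_linked	FALSE	940	FALSE
OTC	x_linked	FALSE	1010	FALSE
ERCC3	dominant	TRUE	2363	FALSE
DLEC1	dominant	TRUE	852	FALSE
FANCC	dominant	TRUE	972	FALSE
FANCM	dominant	TRUE	2463	FALSE
FANCA	dominant	TRUE	1606	FALSE
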