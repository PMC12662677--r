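# One gene per SNP for the packaged candidate tables (static stand-in for a
# variant-to-gene service).  The gene symbol "NA" for rs11255790 is the
# literal printed symbol (no mapped gene) and is kept as a literal string.
snp	gene
rs12409301	CAPZB
rs12855	CDKN2C
rs951366	PM20D1
rs59381142	HES1
rs11755845	VEGFA
rs10814915	GLIS3
rs7045138	TRMO
rs11255790	NA
rs10905868	CELF2
rs4933466	PTEN
rs2475217	SLK
rs643506	PPP2R1B
rs71430783	ITPK1
rs2601803	ADCY9
rs3848445	HS3ST3B1
rs75261749	UTP18
rs9915657	SOX9
rs4552110	CCBE1
rs62143197	NLRP12
rs4666462	OSR1
rs622474	PDE4B
rs11204752	GOLPH3L
rs6722076	UGT1A6
rs6717283	BOK
rs16874919	PPARGC1A
rs6462411	SDK1
rs59282311	PDE7A
rs1441198	SULF1
rs9298749	BNC2
rs925489	TRMO
rs7855088	ANP32B
rs657152	ABO
rs7020640	EGFL7
rs6499766	LPCAT2
rs7253430	ATP8B3
rs1354034	ARHGEF3
rs17122904	PATJ
rs77101060	SORCS1
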