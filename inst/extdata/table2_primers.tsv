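marker	polymorphism	primer	sequence
Gn1a-17SNP	G/A SNP in promoter	Gn1a-17SNP-OPF	TCGCAGGCACTGCACTTCA
Gn1a-17SNP	G/A SNP in promoter	Gn1a-17SNP-OPR	GCCACCCTAGGTTTGATTCC
Gn1a-17SNP	G/A SNP in promoter	Gn1a-17SNP-AF	CATACCTAGCGTTCTATGCtGA
Gn1a-17SNP	G/A SNP in promoter	Gn1a-17SNP-GR	GGAAGATAAAGAAATTTCACATaCC
Gn1a-indel3	~70-bp indel near the 3'UTR	Gn1a-indel3-F	GATCTAGATGCTCCAAAGTCC
Gn1a-indel3	~70-bp indel near the 3'UTR	Gn1a-indel3-R	CTGTACGTACGTGCACGTAG
Gn1a-indel1	16-bp indel in the 5'UTR	Gn1a-indel1-F	GCCACCTTGTCCCTTCTACA
Gn1a-indel1	16-bp indel in the 5'UTR	Gn1a-indel1-R	TGCCATCCTGACCTGCTCT
SPL14-04SNP	C/T SNP in promoter	SPL14-04SNP-F	TAGCCATAGCTTCTGCGTGA
SPL14-04SNP	C/T SNP in promoter	SPL14-04SNP-CR	ACCGTGCTTACCGCCtGG
SPL14-04SNP	C/T SNP in promoter	SPL14-04SNP-TR	ACCGTGCTTACCGCCtGA
SPL14-12SNP	C/A SNP on the third exon	SPL14-12SNP-R	CAAGTGAGACTTCATGTGGT
SPL14-12SNP	C/A SNP on the third exon	SPL14-12SNP-CF	ACCGACTCGAGCTGTGtTC
SPL14-12SNP	C/A SNP on the third exon	SPL14-12SNP-F	GTTCAGAAGCTTTACGTTGGA
SPL14-12SNP	C/A SNP on the third exon	SPL14-12SNP-AR	GCTGGGTTGACAGAAGAGAtAT
SCM2-indel1	12-bp indel in promoter	SCM2-indel1-F	GGAAATGATGAACACTGTCCA
SCM2-indel1	12-bp indel in promoter	SCM2-indel1-R	GTTTGTCTCAGCTCTGATCTG
Ghd7-05SNP	A/T SNP on the second exon	Ghd7-05SNP-F	TGCTTATGCGTACATCTGGAT
Ghd7-05SNP	A/T SNP on the second exon	Ghd7-05SNP-AR	TGGGTTCAAGCTCTCCaCAT
Ghd7-05SNP	A/T SNP on the second exon	Ghd7-05SNP-TR	TGGGTTCAAGCTCTCCaCAA
DEP1-indel1P	625-bp indel on the fifth exon	DEP1-indel1-F	GCAAGTGCTCACCCAAGTG
DEP1-indel1P	625-bp indel on the fifth exon	DEP1-indel1-R	GTTCGAACTTAATCAAAGGCCT
DEP1-indel1P	625-bp indel on the fifth exon	DEP1-indel1-625F	CACGACGCAGTGCTTCAGCT
SPIKE-01SNP	G/A SNP on the third exon	SPIKE-01SNP-GF	GGTTGGTTTCCTCACTAAaCG
SPIKE-01SNP	G/A SNP on the third exon	SPIKE-01SNP-AF	GGTTGGTTTCCTCACTAAaCA
SPIKE-01SNP	G/A SNP on the third exon	SPIKE-01SNP-R	ATGGGAACTAGGAAGCAGGA
SPIKE-03SNP	G/A SNP on the fifth exon	SPIKE-03SNP-F	CTACTCGACCGTCTGGAAC
SPIKE-03SNP	G/A SNP on the fifth exon	SPIKE-03SNP-GR	TGGCTCGAAGATCTCTTCtAC
SPIKE-03SNP	G/A SNP on the fifth exon	SPIKE-03SNP-AR	TGGCTCGAAGATCTCTTCtAT
SPIKE-indel3	~20-bp indel in promoter	SPIKE-indel3-F	GGAGAGACATGGACGGCT
SPIKE-indel3	~20-bp indel in promoter	SPIKE-indel3-R	TGGTGGCGATCATGCTGC
GS5-indel1	4-bp indel in promoter	GS5-indel1-F	CTAACTCCCATGGAATTACTAG
GS5-indel1	4-bp indel in promoter	GS5-indel1-R	GGAAAGCGAAACTGATTGACA
GS5-03SNP	T/C SNP in promoter	GS5-03SNP-OPF	ACTTTCAACTAAAGTGATATTACCTC
GS5-03SNP	T/C SNP in promoter	GS5-03SNP-OPR	TCTATATATCCATCGTCCATGGTGG
GS5-03SNP	T/C SNP in promoter	GS5-03SNP-TF	CGCAGCCTAACTACCTAAGTAGcT
GS5-03SNP	T/C SNP in promoter	GS5-03SNP-CR	ACATGCGTGCCAATATTCCTGTAtTG
TGW6-1d	1-bp indel on the first exon	TGW6-1d-F	GCCAACTGATCAGACTGAG
TGW6-1d	1-bp indel on the first exon	TGW6-1d-NR	CGTGGGGAGAGTCGATtCC
TGW6-1d	1-bp indel on the first exon	TGW6-1d-PR	CGTGGGGAGAGTCGATtCG
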