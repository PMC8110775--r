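gene	pathway
RUNX1	hematopoietic TF
CEBPA	hematopoietic TF
GATA2	hematopoietic TF
NRAS	RAS-RTK
KRAS	RAS-RTK
NF1	RAS-RTK
PTPN11	RAS-RTK
CBL	RAS-RTK
FLT3	RAS-RTK
KIT	RAS-RTK
ASXL1	chromatin
BCOR	chromatin
BCORL1	chromatin
EZH2	chromatin
KMT2A	chromatin
DNMT3A	DNA methylation
TET2	DNA methylation
IDH1	DNA methylation
IDH2	DNA methylation
STAG2	cohesin
SMC1A	cohesin
SMC3	cohesin
RAD21	cohesin
SRSF2	splicing
U2AF1	splicing
SF3B1	splicing
ZRSR2	splicing
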