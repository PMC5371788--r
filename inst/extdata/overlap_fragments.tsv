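name	seq
GFP	ACAGCTCCTCGCCCTTGCTCACCAT
GFP_Celegans	AGTCGACCTGCAGGCATGCAAGCT
mCherry	TATCTTCTTCACCCTTTGAGACCAT
RFP	TATCTTCTTCACCCTTTGAGACCAT
YFP	ACAGCTCCTCGCCCTTGCTCACCAT
tdTomato	TGACCTCCTCGCCCTTGCTCACCAT
Illumina paired end adapter 1	ACACTCTTTCCCTACACGACGCTCTTCCGATCT
Illumina paired end adapter 2	CTCGGCATTCCTGCTGAACCGCTCTTCCGATCT
Illumina paired PCR primer 1	AATGATACGGCGACCACCGAGATCTACACTCTTTCCCTACACGACGCTCTTCCGATCT
Illumina paired PCR primer 2	CAAGCAGAAGACGGCATACGAGATCGGTCTCGGCATTCCTGCTGAACCGCTCTTCCGATCT
Illumina paired sequencing primer 1	ACACTCTTTCCCTACACGACGCTCTTCCGATCT
Illumina paired sequencing primer 2	CGGTCTCGGCATTCCTACTGAACCGCTCTTCCGATCT
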