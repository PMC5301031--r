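>IGHV1-SYN1
AGCTTCGGTGCCCTTCACACGTTACGGCTATACTGTCTTGACTCGCTCAGCCGCCTGAGT
CCGTATATGTAATTGGAGCCCTACTGGCGGCCAGCCGCGGAGCCCCGGTGGTTACCGACC
GACGTGAGCCGACGTTCTAGCGGTTTGTAACGGGGTTTGTGGCGTAGCTACGCTATTACT
CGCAAGCTAGATACTGGGGACCCCATGGCACCACACAAACTTACGGGTGTCATCCGGCCA
AAATATCTCCTCGGGATAAGTAACCACCGGCCCTTGTCTCGGGTTATGCCACTGTACAGG
>IGHV3-SYN21
GATATCGAATACGCTTCGTACTCGGGATGTCCCCTCGATGACCGCGTACGGAGGGCAATG
TCCAAAAACAGGTCTGCCCTTATGAGCTGTCTGCTGTCATCCCACGTCTTTCGAATGGAA
TGAGATGCCACGCCGTTCTGAAGAGGTGAAGTCTATGGGGCTTAAGCGGTCGGTTTTGTA
AGACTGCTCTGTGGAAGCATGGACTGGAACTCAGTCATGAACTATAATTGAGATTGCTGC
CTCGATCGAAAAAGGCAGGTTCATCCGGACACCACTTATAGCGACACTATGTCAAAGAGC
>IGHV3-SYN23
AATCATTCACGCCAGGCACTGATCGGTTATCGTAGATCATGGTAGGTTAAGGGGGACTGT
CTCGGTGTCTCAGTGAGACTGATGGTTCTGTCCATTCTCGACCAGCTAGACTGACACGAA
CAGCTCGTCTGAAGGGTAGATTTACTAATCGTATGAGTATAACACAATCACATATTAGCC
TGCTCGAGCCACATACGGTACAGGCCGAAGATTGTCGGTGCAACAATGCAAGGCCCCTTA
GTTGCTGTAAAGTTCGCCTACCGGATCAATGGACGTCTCATACGATATTGGAGTCTAGCC
>IGHV4-SYN34
AATGGGTTAATGCAAACGCTACAAGTCGATTCCTGACCCGGACACGGAGCTCATAACTGG
GCCAGACGTATGTTTCTTAGCGATTCACGAAGTTGACCTAATTTCATTTGTAAAGTGCTA
CGTCCGGCTAAAGGCGCAGCCGGGCTAGGTAACTTACAATTAAAGAGTAAAAGCGAGGTA
TCTTGATCGTCGTTTTGTCAATCCCCTAAGACTGGAGACGCTAGACTTTCTAGATGCAAC
AGTGTAGAACTTAGTTTCCCCTAATACAAGCCCGTTCCGCTCCGTAGTCTACGCGACCAG
>IGHV6-SYN1
TCGGACCCTTACCAGCCGATAAGTTGAGTCCCCCCGAAAACCCCGAATCTGTTTCTTCAT
ATAGTGGCAGATCTCGAACCGACAGGCTCTATGTAACTAGGGAGCCGTCGCGGCCTGTGG
GATGTATGCAAGGCGGTGTTCTGAATATATGTTCAGTTTGTTCGCAGTTAAGACAATTTC
TCAGAAGAACCATTCGTTGCTCATTGTTTATCTGTCTATGCACTGAAGCGAACGATGCGG
AATGGAGGTTAGATCCTCCGATGTGCGATGGTACAATCAACAGCAGTCCTTCCAACAAAT
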