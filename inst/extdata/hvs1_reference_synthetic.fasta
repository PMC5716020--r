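>HVS1_synthetic coords=16051-16384 synthetic stand-in reference (not rCRS; positions only are meaningful)
TGCCGTATCTTTCGAGGCCTTCTCACGCTCACAGGACTATTACTTTAATTGATATGCCCA
TTATGAATCTTCATCAATACAATAGAACCTCATCTATAAACAAAACTAACACGAACAGTT
TGACTCATTGACCAATTCTACTCTTAAGTCTGAAGAGCTACATCGATATATACTTCCATT
ATGTCTTTTATTTTAAGTATGAAGCTCGGTAGCTAAGCAAGTTATTTCGTTGGTCCCCCA
AAGTCATCTCATACTTTCATGCGTACCATCTCTTCCCACACCTCTTGACTATTGTCGACA
TTGAAACAGCATGTGTAGGACTTCCACCGCCTTA
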