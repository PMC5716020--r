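# Y-chromosome SNP panel (ISOGG-style nested clades).
# Columns (tab separated): node  parent  marker  ancestral  derived
# "." = allele not typed by the packaged panel; such nodes can only be called
# from genotypes given as the literal keywords "derived"/"ancestral".
C	ROOT	M216	C	T
F	ROOT	M89	C	T
K	F	M9	C	G
NO	K	M214	T	C
N	NO	M231	G	A
O	NO	M175	ins	-5bp
O3	O	M122	T	C
O3a	O3	M324	C	G
O3a2	O3a	P201	T	C
O3a2c	O3a2	M134	.	.
O3a2c1a	O3a2c	M117	.	.
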