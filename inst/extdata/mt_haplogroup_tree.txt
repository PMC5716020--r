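# East Asian mtDNA rule tree used for motif + coding-SNP haplogroup calls.
# Columns (tab separated): label  parent  defining-tokens (comma separated).
# Token forms:
#   12345      diagnostic coding position typed derived (allele unspecified)
#   12345T     diagnostic coding position with explicit derived allele
#   del:9bp    special deletion marker (COII/tRNA-Lys 9-bp deletion)
#   !12345     position ancestral, valid only when coding data were typed
#   child      any child node's diagnostic is satisfied (lets a deeper
#              N-side diagnostic outweigh a printed 10400 entry, which the
#              source table lists even for N-clade rows)
#   hvs*a+b    all listed HVS-I positions present (supplementary motif support)
#   hvs=a+b    HVS-I transition set exactly equals the listed positions
#              (low-confidence motif-only assignment)
#   *          star/paraphyletic fallback: parent supported, no sibling matched
M	ROOT	10400
N	ROOT	!10400,child
D	M	5178
D4	D	3010
D5	D	10397
D*	D	*
C	M	14318
G	M	4833
Z	M	15784,hvs*16185+16223+16260+16298
M7	M	6455
M8	M	15487T
M10	M	10646
M13	M	6023
M25	ROOT	hvs=16223+16304
A	N	663
N9a	N	5417
B	N	del:9bp
F	N	3970
N*	N	*
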