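sample_id	population	grave_id	age_bp	sex	hvs1_motif	coding_snps	haplotype_id	haplogroup
MG28	Mogou	grv01	4000	unknown	086-223-290-319-362	10400;663	ht1	A
MG20	Mogou	grv02	4000	unknown	093-129-223-284-290-319-362	10400;663	ht2	A
MG23	Mogou	grv03	4000	unknown	051-129-182C-183C-189-290-319-362	10400;663	ht3	A
MG24	Mogou	grv04	4000	unknown	223-290-311-319-362	10400;663	ht4	A
MG8	Mogou	grv05	4000	unknown	111-140-183C-189-234-243	9bp_del	ht5	B
MG57	Mogou	grv06	4000	unknown	111-140-183C-189-234-243	9bp_del	ht6	B
MG21	Mogou	grv07	4000	unknown	223-298-327	10400;14318	ht7	C
MG37	Mogou	grv08	4000	unknown	223-298-327	10400;14318	ht8	C
MG36	Mogou	grv09	4000	unknown	093-129-223-298-327	10400;14318	ht9	C
MG41	Mogou	grv10	4000	unknown	093-129-188-223-298-327	10400;14318	ht10	C
MG50	Mogou	grv11	4000	unknown	129-192-223-298-327	10400;14318	ht11	C
MG51	Mogou	grv11	4000	unknown	129-192-223-298-327	10400;14318	ht11	C
MG54	Mogou	grv11	4000	unknown	129-192-223-298-327	10400;14318	ht11	C
MG38	Mogou	grv12	4000	unknown	129-223-362	10400;5178	ht12	D*
MG33	Mogou	grv13	4000	unknown	151-223-290-362	10400;5178	ht13	D*
MG11	Mogou	grv14	4000	unknown	223-362	10400;5178;3010	ht14	D4
MG22	Mogou	grv15	4000	unknown	223-362	10400;5178;3010	ht15	D4
MG47	Mogou	grv16	4000	unknown	223-362	10400;5178;3010	ht16	D4
MG52	Mogou	grv16	4000	unknown	223-362	10400;5178;3010	ht16	D4
MG53	Mogou	grv16	4000	male	223-362	10400;5178;3010	ht16	D4
MG3	Mogou	grv17	4000	male	223-274-362	10400;5178;3010	ht17	D4
MG5	Mogou	grv17	4000	unknown	223-274-362	10400;5178;3010	ht17	D4
MG6	Mogou	grv17	4000	unknown	223-274-362	10400;5178;3010	ht17	D4
MG45	Mogou	grv18	4000	unknown	223-274-362	10400;5178;3010	ht18	D4
MG48	Mogou	grv19	4000	male	129-223-274-362	10400;5178;3010	ht19	D4
MG4	Mogou	grv20	4000	unknown	223-311-362	10400;5178;3010	ht20	D4
MG40	Mogou	grv21	4000	unknown	223-343-362	10400;5178;3010	ht21	D4
MG19	Mogou	grv22	4000	unknown	223-292-311-328-362	10400;5178;3010	ht22	D4
MG10	Mogou	grv23	4000	unknown	126-182C-183C-189-223-362	10400;5178;10397	ht23	D5
MG55	Mogou	grv24	4000	unknown	129-164-172-182C-183C-189-223-266-362	10400;5178;10397	ht24	D5
MG58	Mogou	grv25	4000	unknown	129-164-172-182C-183C-189-223-266-362	10400;5178;10397	ht25	D5
MG18	Mogou	grv26	4000	male	092-164-172-182C-183C-189-223-266-362	10400;5178;10397	ht26	D5
MG32	Mogou	grv27	4000	unknown	092-164-172-182C-183C-189-223-266-362	10400;5178;10397	ht27	D5
MG35	Mogou	grv28	4000	unknown	189-304	3970	ht28	F
MG42	Mogou	grv29	4000	unknown	189-304	3970	ht29	F
MG44	Mogou	grv30	4000	male	183C-189-304	3970	ht30	F
MG31	Mogou	grv31	4000	unknown	183C-189-232A-249-304	3970	ht31	F
MG59	Mogou	grv32	4000	unknown	129-223-261-278-311-362	10400;4833	ht32	G
MG43	Mogou	grv33	4000	unknown	086-153-223-278-362	10400;4833	ht33	G
MG25	Mogou	grv34	4000	unknown	223-295-362	10400;6455	ht34	M7
MG27	Mogou	grv35	4000	unknown	223-294-295-362	10400;6455	ht35	M7
MG14	Mogou	grv36	4000	unknown	184-223-298-319	10400;15487T	ht36	M8
MG9	Mogou	grv37	4000	male	223-311	10400;10646	ht37	M10
MG29	Mogou	grv38	4000	unknown	223-311	10400;10646	ht38	M10
MG30	Mogou	grv38	4000	unknown	223-311	10400;10646	ht38	M10
MG49	Mogou	grv39	4000	unknown	093-129-193-223-311-357	10400;10646	ht39	M10
MG39	Mogou	grv40	4000	unknown	145-188-189-192-223-311-381	10400;6023	ht40	M13
MG60	Mogou	grv41	4000	unknown	223-304		ht41	M25
MG2	Mogou	grv42	4000	unknown	223-243-256	10398	ht42	N*
MG7	Mogou	grv43	4000	unknown	114-223-261	5417	ht43	N9a
MG13	Mogou	grv44	4000	unknown	223-257A	5417	ht44	N9a
MG15	Mogou	grv45	4000	unknown	185-223-260-298	10400;15784	ht45	Z
MG16	Mogou	grv45	4000	unknown	185-223-260-298	10400;15784	ht45	Z
MG17	Mogou	grv45	4000	unknown	185-223-260-298	10400;15784	ht45	Z
MG12	Mogou	grv46	4000	unknown	185-223-259-260-298	10400;15784	ht46	Z
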