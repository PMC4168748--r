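col	a1_pos	a1_aa	a1_snv	fus_pos	fus_aa	fus_mut	starred
1	262	D	.	NA	.	.	FALSE
2	263	F	L	NA	.	.	FALSE
3	264	G	.	NA	.	.	FALSE
4	265	N	D	NA	.	.	FALSE
5	266	Y	.	NA	.	.	FALSE
6	267	N	.	NA	.	.	FALSE
7	268	N	.	NA	.	.	FALSE
8	269	Q	.	NA	.	.	FALSE
9	270	S	.	NA	.	.	FALSE
10	271	S	.	NA	.	.	FALSE
11	272	N	.	507	G	D	FALSE
12	273	F	L	508	P	.	FALSE
13	274	G	.	509	G	.	FALSE
14	275	P	S	510	K	E/R	TRUE
15	276	M	L	511	M	.	FALSE
16	277	K	N	512	D	.	FALSE
17	278	G	.	513	S	P	FALSE
18	279	G	.	514	R	G/S	FALSE
19	280	N	S	515	G	C	FALSE
20	281	F	L	516	E	V	FALSE
21	282	G	.	517	H	P/Q	FALSE
22	283	G	.	518	R	G/K	FALSE
23	NA	-	.	519	Q	.	FALSE
24	NA	-	.	520	D	.	FALSE
25	NA	-	.	521	R	G/H/L	FALSE
26	284	R	G	522	R	G	TRUE
27	285	S	G	NA	-	.	FALSE
28	286	S	.	523	E	.	FALSE
29	287	G	.	524	R	S/T/W	FALSE
30	288	P	.	525	P	L	FALSE
31	289	Y	.	526	Y	.	FALSE
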