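property_id	name	source_tag	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
1	Hydrophobicity scales	AAindex CIDH920105 (Cid et al. 1992)	0.02	0.77	-1.04	-1.14	1.35	-0.8	0.26	1.81	-0.41	1.14	1	-0.77	-0.09	-1.1	-0.42	-0.97	-0.77	1.13	1.71	1.11
2	Average flexibility indices	AAindex BHAR880101 (Bhaskaran & Ponnuswamy 1988)	0.357	0.346	0.511	0.497	0.314	0.544	0.323	0.462	0.466	0.365	0.295	0.463	0.509	0.493	0.529	0.507	0.444	0.386	0.305	0.42
3	Polarizability parameter	AAindex CHAM820101 (Charton & Charton 1982)	0.046	0.128	0.105	0.151	0.29	0	0.23	0.186	0.219	0.186	0.221	0.134	0.131	0.18	0.291	0.062	0.108	0.14	0.409	0.298
4	Free energy of solution in water	AAindex CHAM820102 (Charton & Charton 1982)	-0.368	4.53	2.06	1.77	1.06	-0.525	0	0.791	0	1.07	0.656	0	-2.24	0.731	-1.03	-0.524	0	0.401	1.6	4.91
5	Residue accessible surface area in tripeptide	AAindex CHOC760101 (Chothia 1976)	115	135	150	190	210	75	195	175	200	170	185	160	145	180	225	115	140	155	255	230
6	Residue volume	AAindex BIGC670101 (Bigelow 1967)	52.6	68.3	68.4	84.7	113.9	36.3	91.9	102	105.1	102	97.7	75.7	73.6	89.7	109.1	54.9	71.2	85.1	135.4	116.2
7	Steric parameter	AAindex CHAM810101 (Charton 1981)	0.52	0.62	0.76	0.68	0.7	0	0.7	1.02	0.68	0.98	0.78	0.76	0.36	0.68	0.68	0.53	0.5	0.76	0.7	0.7
8	Relative mutability	AAindex DAYM780201 (Dayhoff et al. 1978)	100	20	106	102	41	49	66	96	56	40	94	134	56	93	65	120	97	74	18	41
9	Hydrophobicity	Tanford scale as used in Chou's PseAAC	0.62	0.29	-0.9	-0.74	1.19	0.48	-0.4	1.38	-1.5	1.06	0.64	-0.78	0.12	-0.85	-2.53	-0.18	-0.05	1.08	0.81	0.26
10	Hydrophilicity	Hopp-Woods scale as used in Chou's PseAAC	-0.5	-1	3	3	-2.5	0	-0.5	-1.8	3	-1.8	-1.3	0.2	0	0.2	3	0.3	-0.4	-1.5	-3.4	-2.3
11	Side-chain mass	residue side-chain masses as used in Chou's PseAAC	15	47	59	73	91	1	82	57	73	57	75	58	42	72	101	31	45	43	130	107
12	Normalized van der Waals volume	Fauchere et al. 1988 normalized vdW volume	1	2.43	2.78	3.78	5.89	0	4.66	4	4.77	4	4.43	2.95	2.72	3.95	6.13	1.6	2.6	3	8.08	6.47
13	Polarity	Grantham 1974 polarity	8.1	5.5	13	12.3	5.2	9	10.4	5.2	11.3	4.9	5.7	11.6	8	10.5	10.5	9.2	8.6	5.9	5.4	6.2
14	Polarizability	Charton & Charton 1982 polarizability	0.046	0.128	0.105	0.151	0.29	0	0.23	0.186	0.219	0.186	0.221	0.134	0.131	0.18	0.291	0.062	0.108	0.14	0.409	0.298
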