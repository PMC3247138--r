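property_id	name	group	label	members
12	Normalized van der Waals volume	1	small	GASTPDC
12	Normalized van der Waals volume	2	medium	NVEQIL
12	Normalized van der Waals volume	3	large	MHKFRYW
13	Polarity	1	low	LIFWCMVY
13	Polarity	2	medium	PATGS
13	Polarity	3	high	HQRKNED
14	Polarizability	1	low	GASDT
14	Polarizability	2	medium	CPNVEQIL
14	Polarizability	3	high	KMHFRYW
15	Charge	1	positive	KR
15	Charge	2	neutral	ANCQGHILMFPSTWYV
15	Charge	3	negative	DE
16	Secondary structure	1	helix	EALMQKRH
16	Secondary structure	2	strand	VIYCWFT
16	Secondary structure	3	coil	GNPSD
17	Solvent accessibility	1	buried	ALFCGIVW
17	Solvent accessibility	2	exposed	RKQEND
17	Solvent accessibility	3	intermediate	MSPTHY
18	Relative hydrophobicity	1	polar	RKEDQN
18	Relative hydrophobicity	2	neutral	GASTPHY
18	Relative hydrophobicity	3	hydrophobic	CLVIMFW
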