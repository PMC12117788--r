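aa	atom	ref_a	ref_b	ref_c	bond	angle	chi	offset
SER	OG	N	CA	CB	1.417	110.8	1	0
CYS	SG	N	CA	CB	1.808	114.4	1	0
THR	OG1	N	CA	CB	1.433	109.6	1	0
THR	CG2	N	CA	CB	1.521	110.5	1	-122
VAL	CG1	N	CA	CB	1.527	110.5	1	0
VAL	CG2	N	CA	CB	1.527	110.5	1	-122
LEU	CG	N	CA	CB	1.530	116.3	1	0
LEU	CD1	CA	CB	CG	1.524	110.7	2	0
LEU	CD2	CA	CB	CG	1.525	110.4	2	122
ILE	CG1	N	CA	CB	1.530	110.4	1	0
ILE	CG2	N	CA	CB	1.521	110.5	1	-122
ILE	CD1	CA	CB	CG1	1.513	113.8	2	0
MET	CG	N	CA	CB	1.520	114.1	1	0
MET	SD	CA	CB	CG	1.803	112.7	2	0
MET	CE	CB	CG	SD	1.791	100.9	3	0
PHE	CG	N	CA	CB	1.502	113.8	1	0
PHE	CD1	CA	CB	CG	1.384	120.8	2	0
PHE	CD2	CA	CB	CG	1.384	120.8	2	180
PHE	CE1	CB	CG	CD1	1.382	121.2	0	180
PHE	CE2	CB	CG	CD2	1.382	121.2	0	180
PHE	CZ	CG	CD1	CE1	1.372	120.1	0	0
TYR	CG	N	CA	CB	1.502	113.8	1	0
TYR	CD1	CA	CB	CG	1.384	120.8	2	0
TYR	CD2	CA	CB	CG	1.384	120.8	2	180
TYR	CE1	CB	CG	CD1	1.382	121.2	0	180
TYR	CE2	CB	CG	CD2	1.382	121.2	0	180
TYR	CZ	CG	CD1	CE1	1.372	120.1	0	0
TYR	OH	CD1	CE1	CZ	1.376	119.9	0	180
TRP	CG	N	CA	CB	1.498	113.6	1	0
TRP	CD1	CA	CB	CG	1.365	126.9	2	0
TRP	CD2	CA	CB	CG	1.433	126.7	2	180
TRP	NE1	CB	CG	CD1	1.374	110.1	0	180
TRP	CE2	CD1	CG	CD2	1.409	107.2	0	0
TRP	CE3	CD1	CG	CD2	1.398	133.9	0	180
TRP	CZ2	CG	CD2	CE2	1.394	122.4	0	180
TRP	CZ3	CG	CD2	CE3	1.382	118.6	0	180
TRP	CH2	CD2	CE2	CZ2	1.368	117.5	0	0
ASP	CG	N	CA	CB	1.516	113.0	1	0
ASP	OD1	CA	CB	CG	1.249	118.4	2	0
ASP	OD2	CA	CB	CG	1.249	118.4	2	180
ASN	CG	N	CA	CB	1.516	112.7	1	0
ASN	OD1	CA	CB	CG	1.231	120.8	2	0
ASN	ND2	CA	CB	CG	1.328	116.4	2	180
GLU	CG	N	CA	CB	1.520	114.1	1	0
GLU	CD	CA	CB	CG	1.516	112.6	2	0
GLU	OE1	CB	CG	CD	1.249	118.4	3	0
GLU	OE2	CB	CG	CD	1.249	118.4	3	180
GLN	CG	N	CA	CB	1.520	114.1	1	0
GLN	CD	CA	CB	CG	1.516	112.6	2	0
GLN	OE1	CB	CG	CD	1.231	120.8	3	0
GLN	NE2	CB	CG	CD	1.328	116.4	3	180
LYS	CG	N	CA	CB	1.520	114.1	1	0
LYS	CD	CA	CB	CG	1.520	111.3	2	0
LYS	CE	CB	CG	CD	1.520	111.3	3	0
LYS	NZ	CG	CD	CE	1.489	111.9	4	0
ARG	CG	N	CA	CB	1.520	114.1	1	0
ARG	CD	CA	CB	CG	1.520	111.3	2	0
ARG	NE	CB	CG	CD	1.461	112.0	3	0
ARG	CZ	CG	CD	NE	1.329	124.2	4	0
ARG	NH1	CD	NE	CZ	1.326	120.3	0	0
ARG	NH2	CD	NE	CZ	1.326	120.3	0	180
HIS	CG	N	CA	CB	1.497	113.8	1	0
HIS	ND1	CA	CB	CG	1.378	122.7	2	0
HIS	CD2	CA	CB	CG	1.354	129.7	2	180
HIS	CE1	CB	CG	ND1	1.320	109.2	0	180
HIS	NE2	CB	CG	CD2	1.374	107.2	0	180
PRO	CG	N	CA	CB	1.495	104.5	1	0
PRO	CD	CA	CB	CG	1.507	106.1	2	0
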