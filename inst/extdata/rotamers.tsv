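aa	rot	chi1	chi2	chi3	chi4	prob
ALA	1	NA	NA	NA	NA	1.00
GLY	1	NA	NA	NA	NA	1.00
SER	1	62	NA	NA	NA	0.48
SER	2	-65	NA	NA	NA	0.30
SER	3	-177	NA	NA	NA	0.22
CYS	1	-65	NA	NA	NA	0.55
CYS	2	-177	NA	NA	NA	0.26
CYS	3	62	NA	NA	NA	0.19
THR	1	62	NA	NA	NA	0.49
THR	2	-65	NA	NA	NA	0.43
THR	3	-175	NA	NA	NA	0.08
VAL	1	175	NA	NA	NA	0.73
VAL	2	-60	NA	NA	NA	0.20
VAL	3	63	NA	NA	NA	0.07
LEU	1	-65	175	NA	NA	0.62
LEU	2	-177	65	NA	NA	0.29
LEU	3	-85	65	NA	NA	0.09
ILE	1	-65	170	NA	NA	0.62
ILE	2	-57	-60	NA	NA	0.19
ILE	3	-177	165	NA	NA	0.19
MET	1	-65	-65	-70	NA	0.40
MET	2	-65	-65	180	NA	0.30
MET	3	-177	180	75	NA	0.30
PHE	1	-65	90	NA	NA	0.44
PHE	2	-177	80	NA	NA	0.33
PHE	3	62	90	NA	NA	0.23
TYR	1	-65	90	NA	NA	0.44
TYR	2	-177	80	NA	NA	0.33
TYR	3	62	90	NA	NA	0.23
TRP	1	-65	95	NA	NA	0.35
TRP	2	-177	-105	NA	NA	0.20
TRP	3	62	-90	NA	NA	0.20
TRP	4	-65	-5	NA	NA	0.25
ASP	1	-70	-15	NA	NA	0.51
ASP	2	-177	5	NA	NA	0.29
ASP	3	62	-10	NA	NA	0.20
ASN	1	-65	-20	NA	NA	0.47
ASN	2	-177	30	NA	NA	0.28
ASN	3	62	-75	NA	NA	0.25
GLU	1	-65	-65	-40	NA	0.40
GLU	2	-177	180	0	NA	0.35
GLU	3	-65	180	0	NA	0.25
GLN	1	-65	-65	-40	NA	0.44
GLN	2	-177	180	20	NA	0.31
GLN	3	-65	180	0	NA	0.25
LYS	1	-67	180	180	180	0.40
LYS	2	-177	180	180	180	0.30
LYS	3	-65	-65	180	180	0.30
ARG	1	-67	180	180	180	0.35
ARG	2	-177	180	65	85	0.25
ARG	3	-65	-65	-65	180	0.20
ARG	4	62	180	65	85	0.20
HIS	1	-65	-70	NA	NA	0.35
HIS	2	-177	60	NA	NA	0.30
HIS	3	62	-75	NA	NA	0.35
PRO	1	30	-35	NA	NA	0.50
PRO	2	-25	35	NA	NA	0.50
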