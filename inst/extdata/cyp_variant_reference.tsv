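variant	enzyme	adme_score	bin_lo	bin_hi	call	mean_pct	sd_pct
F114C	CYP2C19	0.8	0	10	D	18.8	10.7
C164G	CYP2C19	0.8	0	10	D	26.3	9.5
R186H	CYP2C19	0.6	20	30	D	20.7	6.3
H251Q	CYP2C19	0.8	0	10	D	3.7	5.8
K275M	CYP2C19	0.8	0	10	D	36.6	5.8
A297V	CYP2C19	1.0	0	0	D	2.9	4.4
M339T	CYP2C19	0.6	20	30	D	70.6	35.1
R133C	CYP2D6	1.0	0	0	D	4.6	2.6
D301N	CYP2D6	0.6	20	30	D	0.9	0.9
A305T	CYP2D6	1.0	0	0	D	9.6	3.3
L314M	CYP2D6	0.8	0	10	D	58.7	24.0
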