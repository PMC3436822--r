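# Backbone-independent side-chain rotamer library, condensed snapshot v1.
# One row per rotamer: modal chi means (degrees, IUPAC convention), per-chi
# admission half-widths (degrees; a rotamer admits an observation only when
# every |delta chi| <= half-width) and approximate occurrence frequencies used
# solely for tie-breaking.  Terminal chis with 2-fold symmetric end groups
# (Asp chi2, Glu chi3, Phe/Tyr chi2) are stored on (-90, 90] and compared
# modulo 180 degrees.
res_type	rotamer	nchi	chi1	chi2	chi3	chi4	hw1	hw2	hw3	hw4	freq
SER	p	1	62	NA	NA	NA	30	NA	NA	NA	0.48
SER	t	1	-177	NA	NA	NA	30	NA	NA	NA	0.22
SER	m	1	-65	NA	NA	NA	30	NA	NA	NA	0.29
THR	p	1	62	NA	NA	NA	30	NA	NA	NA	0.49
THR	t	1	-175	NA	NA	NA	30	NA	NA	NA	0.07
THR	m	1	-65	NA	NA	NA	30	NA	NA	NA	0.43
CYS	p	1	62	NA	NA	NA	30	NA	NA	NA	0.23
CYS	t	1	-177	NA	NA	NA	30	NA	NA	NA	0.26
CYS	m	1	-65	NA	NA	NA	30	NA	NA	NA	0.50
VAL	p	1	63	NA	NA	NA	30	NA	NA	NA	0.06
VAL	t	1	175	NA	NA	NA	30	NA	NA	NA	0.73
VAL	m	1	-60	NA	NA	NA	30	NA	NA	NA	0.20
ILE	pt	2	62	170	NA	NA	30	30	NA	NA	0.08
ILE	tt	2	-177	170	NA	NA	30	30	NA	NA	0.08
ILE	mt	2	-65	170	NA	NA	30	30	NA	NA	0.60
ILE	mm	2	-65	-65	NA	NA	30	30	NA	NA	0.15
LEU	mt	2	-65	175	NA	NA	30	30	NA	NA	0.62
LEU	tp	2	-177	65	NA	NA	30	30	NA	NA	0.29
LEU	tt	2	-177	175	NA	NA	30	30	NA	NA	0.02
PRO	Cg_endo	1	30	NA	NA	NA	30	NA	NA	NA	0.44
PRO	Cg_exo	1	-30	NA	NA	NA	30	NA	NA	NA	0.56
ASP	m-20	2	-70	-20	NA	NA	30	30	NA	NA	0.51
ASP	t0	2	-177	0	NA	NA	30	30	NA	NA	0.23
ASP	p-10	2	62	-10	NA	NA	30	30	NA	NA	0.26
ASN	p-10	2	62	-10	NA	NA	30	30	NA	NA	0.09
ASN	t-20	2	-174	-20	NA	NA	30	30	NA	NA	0.33
ASN	m-40	2	-65	-40	NA	NA	30	30	NA	NA	0.45
GLU	mt-10	3	-67	177	-10	NA	30	30	30	NA	0.35
GLU	tt0	3	-177	177	0	NA	30	30	30	NA	0.24
GLU	mm-40	3	-65	-58	-40	NA	30	30	30	NA	0.13
GLU	pt-20	3	62	180	-20	NA	30	30	30	NA	0.08
GLN	mt-30	3	-67	177	-30	NA	30	30	30	NA	0.38
GLN	mm-40	3	-65	-60	-40	NA	30	30	30	NA	0.14
GLN	pt20	3	62	180	20	NA	30	30	30	NA	0.07
GLN	tt0	3	-177	177	0	NA	30	30	30	NA	0.16
MET	mtp	3	-67	180	75	NA	30	30	30	NA	0.21
MET	mtm	3	-67	180	-75	NA	30	30	30	NA	0.20
MET	mmm	3	-65	-65	-70	NA	30	30	30	NA	0.18
MET	ttp	3	-177	180	75	NA	30	30	30	NA	0.10
LYS	mttt	4	-67	180	180	180	30	30	30	30	0.25
LYS	tttt	4	-177	180	180	180	30	30	30	30	0.18
LYS	mttp	4	-67	180	180	65	30	30	30	30	0.08
LYS	mttm	4	-67	180	180	-65	30	30	30	30	0.08
LYS	mmtt	4	-65	-68	180	180	30	30	30	30	0.09
ARG	mtt180	4	-67	180	180	180	30	30	30	30	0.13
ARG	mtt85	4	-67	180	180	85	30	30	30	30	0.10
ARG	mtt-85	4	-67	180	180	-85	30	30	30	30	0.10
ARG	ttt180	4	-177	180	180	180	30	30	30	30	0.08
ARG	mmt180	4	-65	-68	180	180	30	30	30	30	0.07
HIS	m-70	2	-65	-70	NA	NA	30	30	NA	NA	0.29
HIS	m170	2	-65	165	NA	NA	30	30	NA	NA	0.13
HIS	t60	2	-177	65	NA	NA	30	30	NA	NA	0.13
HIS	t-80	2	-177	-80	NA	NA	30	30	NA	NA	0.11
HIS	p80	2	62	80	NA	NA	30	30	NA	NA	0.09
PHE	m-85	2	-65	-85	NA	NA	30	30	NA	NA	0.44
PHE	t80	2	-177	80	NA	NA	30	30	NA	NA	0.33
PHE	p90	2	62	90	NA	NA	30	30	NA	NA	0.13
TYR	m-85	2	-65	-85	NA	NA	30	30	NA	NA	0.43
TYR	t80	2	-177	80	NA	NA	30	30	NA	NA	0.34
TYR	p90	2	62	90	NA	NA	30	30	NA	NA	0.13
TRP	p-90	2	62	-90	NA	NA	30	30	NA	NA	0.11
TRP	t-105	2	-177	-105	NA	NA	30	30	NA	NA	0.16
TRP	t90	2	-177	90	NA	NA	30	30	NA	NA	0.16
TRP	m95	2	-65	95	NA	NA	30	30	NA	NA	0.32
TRP	m-5	2	-65	-5	NA	NA	30	30	NA	NA	0.05
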