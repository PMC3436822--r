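# SYNTHETIC side-chain configurational-entropy table.
# Stand-in for a published delta-S scale (change of side-chain conformational
# entropy upon burial/binding, cal mol^-1 K^-1).  Values were constructed, not
# measured: they follow the qualitative rule that entropy loss grows with the
# number of rotatable side-chain bonds.  Replace with a published table for
# real analyses; the entropy-correlation function accepts any two-column TSV.
res_type	delta_s
CYS	1.0
VAL	1.1
THR	1.2
TRP	2.0
HIS	2.1
LEU	2.2
ILE	2.3
SER	2.6
ASP	2.7
PHE	2.8
TYR	2.9
ASN	3.1
GLU	3.4
MET	4.2
GLN	4.4
ARG	4.6
LYS	5.0
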