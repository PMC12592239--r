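codon	amino_acid	freq
TTT	F	0.25
TTC	F	0.75
TTA	L	0.03571428571428571
TTG	L	0.10714285714285714
TCT	S	0.08333333333333333
TCC	S	0.25
TCA	S	0.08333333333333333
TCG	S	0.25
TAT	Y	0.25
TAC	Y	0.75
TAA	*	0.14285714285714285
TAG	*	0.42857142857142855
TGT	C	0.25
TGC	C	0.75
TGA	*	0.42857142857142855
TGG	W	1
CTT	L	0.10714285714285714
CTC	L	0.32142857142857145
CTA	L	0.10714285714285714
CTG	L	0.32142857142857145
CCT	P	0.125
CCC	P	0.375
CCA	P	0.125
CCG	P	0.375
CAT	H	0.25
CAC	H	0.75
CAA	Q	0.25
CAG	Q	0.75
CGT	R	0.10714285714285714
CGC	R	0.32142857142857145
CGA	R	0.10714285714285714
CGG	R	0.32142857142857145
ATT	I	0.2
ATC	I	0.6
ATA	I	0.2
ATG	M	1
ACT	T	0.125
ACC	T	0.375
ACA	T	0.125
ACG	T	0.375
AAT	N	0.25
AAC	N	0.75
AAA	K	0.25
AAG	K	0.75
AGT	S	0.08333333333333333
AGC	S	0.25
AGA	R	0.03571428571428571
AGG	R	0.10714285714285714
GTT	V	0.125
GTC	V	0.375
GTA	V	0.125
GTG	V	0.375
GCT	A	0.125
GCC	A	0.375
GCA	A	0.125
GCG	A	0.375
GAT	D	0.25
GAC	D	0.75
GAA	E	0.25
GAG	E	0.75
GGT	G	0.125
GGC	G	0.375
GGA	G	0.125
GGG	G	0.375
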