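# Synthetic tRNA gene copy counts per anticodon (not measured data).
# Structured like a budding-yeast tRNA gene set: one decoder per codon-box
# amino-acid group under standard wobble rules, with arbitrary copy numbers.
# Replace with organism-specific counts for real analyses.
anticodon	copies	amino_acid
GAA	1	F
UAA	5	L
AGA	1	S
CGA	9	S
GUA	10	Y
GCA	4	C
CCA	2	W
AAG	10	L
CAG	1	L
AGG	16	P
CGG	15	P
GUG	8	H
UUG	7	Q
ACG	4	R
CCG	9	R
AAU	5	I
CAU	14	M
AGU	4	T
CGU	10	T
GUU	2	N
UUU	15	K
GCU	3	S
UCU	9	R
AAC	9	V
CAC	11	V
AGC	4	A
CGC	5	A
GUC	15	D
UUC	13	E
ACC	5	G
CCC	4	G
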