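# table: hydrophobicity
# source: Monera, Sereda, Zhou, Kay & Hodges (1995) J Pept Sci 1:319-329; side-chain hydrophobicity at pH 7 (study of hydrophobicity and alpha-helical propensity)
# columns: aa, value (relative hydrophobicity, Gly = 0)
# checksum: 505.000000
aa	value
A	41
C	49
D	-55
E	-31
F	100
G	0
H	8
I	99
K	-23
L	97
M	74
N	-28
P	-46
Q	-10
R	-14
S	-5
T	13
V	76
W	97
Y	63
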