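# table: beta_contact
# SYNTHETIC stand-in: constructed deterministically for this package, not transcribed from the literature.
# emulates a cross-strand beta-sheet pairing potential (favourable strand-former pairings); replace with a transcribed published table to reproduce literature values
# symmetric: entry(a,b) == entry(b,a); unordered pairs listed with a <= b alphabetically
# checksum: -88.035000
a	b	value
A	A	-0.064
A	C	-0.349
A	D	0.205
A	E	0.360
A	F	-0.464
A	G	-0.016
A	H	-0.102
A	I	-0.694
A	K	0.034
A	L	-0.417
A	M	-0.195
A	N	-0.138
A	P	0.158
A	Q	-0.284
A	R	-0.129
A	S	0.035
A	T	-0.317
A	V	-0.726
A	W	-0.527
A	Y	-0.596
C	C	-0.760
C	D	0.030
C	E	0.161
C	F	-1.024
C	G	-0.257
C	H	-0.383
C	I	-1.235
C	K	-0.195
C	L	-0.933
C	M	-0.619
C	N	-0.411
C	P	0.011
C	Q	-0.627
C	R	-0.497
C	S	-0.265
C	T	-0.772
C	V	-1.362
C	W	-0.952
C	Y	-1.143
D	D	0.312
D	E	0.424
D	F	-0.101
D	G	0.259
D	H	0.214
D	I	-0.249
D	K	0.235
D	L	-0.047
D	M	0.108
D	N	0.125
D	P	0.329
D	Q	0.052
D	R	0.164
D	S	0.281
D	T	-0.026
D	V	-0.281
D	W	-0.083
D	Y	-0.117
E	E	0.510
E	F	0.159
E	G	0.326
E	H	0.305
E	I	0.058
E	K	0.399
E	L	0.126
E	M	0.241
E	N	0.324
E	P	0.472
E	Q	0.203
E	R	0.289
E	S	0.378
E	T	0.239
E	V	-0.016
E	W	0.129
E	Y	0.115
F	F	-1.297
F	G	-0.402
F	H	-0.542
F	I	-1.523
F	K	-0.399
F	L	-1.146
F	M	-0.775
F	N	-0.617
F	P	-0.122
F	Q	-0.855
F	R	-0.683
F	S	-0.409
F	T	-0.990
F	V	-1.668
F	W	-1.276
F	Y	-1.388
G	G	0.099
G	H	-0.050
G	I	-0.569
G	K	0.105
G	L	-0.375
G	M	-0.159
G	N	-0.010
G	P	0.274
G	Q	-0.198
G	R	-0.042
G	S	0.122
G	T	-0.267
G	V	-0.621
G	W	-0.345
G	Y	-0.480
H	H	-0.123
H	I	-0.726
H	K	-0.035
H	L	-0.490
H	M	-0.240
H	N	-0.158
H	P	0.169
H	Q	-0.277
H	R	-0.186
H	S	0.003
H	T	-0.348
H	V	-0.849
H	W	-0.530
H	Y	-0.674
I	I	-1.948
I	K	-0.537
I	L	-1.398
I	M	-1.052
I	N	-0.761
I	P	-0.271
I	Q	-1.116
I	R	-0.809
I	S	-0.575
I	T	-1.244
I	V	-2.114
I	W	-1.551
I	Y	-1.676
K	K	0.137
K	L	-0.328
K	M	-0.105
K	N	-0.038
K	P	0.252
K	Q	-0.206
K	R	-0.042
K	S	0.129
K	T	-0.248
K	V	-0.587
K	W	-0.394
K	Y	-0.430
L	L	-1.015
L	M	-0.738
L	N	-0.489
L	P	-0.095
L	Q	-0.769
L	R	-0.596
L	S	-0.321
L	T	-0.941
L	V	-1.563
L	W	-1.093
L	Y	-1.271
M	M	-0.432
M	N	-0.309
M	P	0.092
M	Q	-0.530
M	R	-0.308
M	S	-0.164
M	T	-0.582
M	V	-1.162
M	W	-0.772
M	Y	-0.922
N	N	-0.119
N	P	0.141
N	Q	-0.301
N	R	-0.192
N	S	0.016
N	T	-0.418
N	V	-0.825
N	W	-0.573
N	Y	-0.704
P	P	0.378
P	Q	0.037
P	R	0.091
P	S	0.240
P	T	-0.040
P	V	-0.271
P	W	-0.129
P	Y	-0.134
Q	Q	-0.604
Q	R	-0.364
Q	S	-0.202
Q	T	-0.633
Q	V	-1.230
Q	W	-0.903
Q	Y	-0.960
R	R	-0.239
R	S	-0.016
R	T	-0.458
R	V	-0.965
R	W	-0.602
R	Y	-0.728
S	S	0.089
S	T	-0.270
S	V	-0.594
S	W	-0.377
S	Y	-0.482
T	T	-0.732
T	V	-1.366
T	W	-1.000
T	Y	-1.146
V	V	-2.257
V	W	-1.720
V	Y	-1.825
W	W	-1.200
W	Y	-1.358
Y	Y	-1.523
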