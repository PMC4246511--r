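# table: interface_contact
# SYNTHETIC stand-in: constructed deterministically for this package, not transcribed from the literature.
# emulates a protein-protein interface contact potential (favourable hydrophobic-hydrophobic contacts); replace with a transcribed published table to reproduce literature values
# symmetric: entry(a,b) == entry(b,a); unordered pairs listed with a <= b alphabetically
# checksum: -20.485000
a	b	value
A	A	-0.352
A	C	-0.408
A	D	0.431
A	E	0.247
A	F	-0.792
A	G	0.015
A	H	-0.040
A	I	-0.760
A	K	0.223
A	L	-0.728
A	M	-0.536
A	N	0.190
A	P	0.342
A	Q	0.062
A	R	0.102
A	S	0.038
A	T	-0.097
A	V	-0.593
A	W	-0.753
A	Y	-0.473
C	C	-0.468
C	D	0.441
C	E	0.242
C	F	-0.883
C	G	-0.008
C	H	-0.068
C	I	-0.847
C	K	0.218
C	L	-0.909
C	M	-0.701
C	N	0.191
C	P	0.356
C	Q	0.053
C	R	0.097
C	S	0.028
C	T	-0.119
C	V	-0.655
C	W	-0.828
C	Y	-0.622
D	D	0.451
D	E	0.461
D	F	0.471
D	G	0.481
D	H	0.491
D	I	0.404
D	K	0.414
D	L	0.424
D	M	0.434
D	N	0.444
D	P	0.454
D	Q	0.464
D	R	0.474
D	S	0.484
D	T	0.494
D	V	0.407
D	W	0.417
D	Y	0.427
E	E	0.424
E	F	0.173
E	G	0.384
E	H	0.282
E	I	0.111
E	K	0.366
E	L	0.137
E	M	0.194
E	N	0.409
E	P	0.456
E	Q	0.395
E	R	0.414
E	S	0.310
E	T	0.285
E	V	0.170
E	W	0.139
E	Y	0.218
F	F	-1.505
F	G	-0.300
F	H	-0.391
F	I	-1.553
F	K	0.033
F	L	-1.503
F	M	-1.195
F	N	0.134
F	P	0.378
F	Q	-0.172
F	R	-0.108
F	S	-0.212
F	T	-0.432
F	V	-1.233
F	W	-1.492
F	Y	-1.042
G	G	0.171
G	H	0.148
G	I	-0.256
G	K	0.315
G	L	-0.221
G	M	-0.103
G	N	0.280
G	P	0.376
G	Q	0.224
G	R	0.255
G	S	0.227
G	T	0.158
G	V	-0.118
G	W	-0.201
G	Y	-0.129
H	H	0.120
H	I	-0.344
H	K	0.310
H	L	-0.305
H	M	-0.268
H	N	0.281
H	P	0.390
H	Q	0.215
H	R	0.250
H	S	0.217
H	T	0.136
H	V	-0.277
H	W	-0.373
H	Y	-0.181
I	I	-1.495
I	K	0.084
I	L	-1.537
I	M	-1.227
I	N	0.096
I	P	0.342
I	Q	-0.105
I	R	-0.039
I	S	-0.236
I	T	-0.452
I	V	-1.244
I	W	-1.499
I	Y	-1.048
K	K	0.328
K	L	0.024
K	M	0.101
K	N	0.389
K	P	0.453
K	Q	0.373
K	R	0.303
K	S	0.295
K	T	0.263
K	V	0.111
K	W	0.071
K	Y	0.178
L	L	-1.477
L	M	-1.169
L	N	0.138
L	P	0.286
L	Q	-0.152
L	R	-0.085
L	S	-0.182
L	T	-0.392
L	V	-1.173
L	W	-1.518
L	Y	-1.071
M	M	-0.904
M	N	0.112
M	P	0.323
M	Q	-0.045
M	R	0.016
M	S	-0.063
M	T	-0.238
M	V	-0.994
M	W	-1.201
M	Y	-0.818
N	N	0.360
N	P	0.420
N	Q	0.358
N	R	0.386
N	S	0.288
N	T	0.266
N	V	0.144
N	W	0.115
N	Y	0.211
P	P	0.453
P	Q	0.446
P	R	0.372
P	S	0.386
P	T	0.392
P	V	0.365
P	W	0.369
P	Y	0.318
Q	Q	0.235
Q	R	0.271
Q	S	0.259
Q	T	0.212
Q	V	-0.003
Q	W	-0.157
Q	Y	-0.009
R	R	0.307
R	S	0.298
R	T	0.259
R	V	-0.031
R	W	-0.081
R	Y	0.057
S	S	0.284
S	T	0.135
S	V	-0.104
S	W	-0.169
S	Y	-0.004
T	T	0.057
T	V	-0.276
T	W	-0.370
T	Y	-0.251
V	V	-0.938
V	W	-1.239
V	Y	-0.843
W	W	-1.478
W	Y	-1.022
Y	Y	-0.758
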