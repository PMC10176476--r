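1	0
2	0
3	0
4	0
5	0
6	0
7	0
8	0
9	0
10	0
11	0
12	0
-	0
,	0
di	0
tri	0
tetra	0
ine	0
ene	0
yl	0
oph	0
o	0
chlor	1
brom	1
fluor	1
iod	1
meth	1
amin	1
nitr	1
hydroxy	1
ol	1
benz	1
benzo	1
naphthal	1
pyrid	1
per	1
thi	1
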