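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
13	0
14	0
15	0
16	0
17	0
18	0
19	0
20	0
21	0
22	0
23	0
24	0
25	0
26	0
27	0
28	0
29	0
30	0
31	0
32	0
33	0
34	0
35	0
36	0
37	0
38	0
39	0
40	0
41	0
42	0
43	0
44	0
45	0
46	0
47	0
48	0
49	0
50	0
-	0
,	0
(	0
)	0
[	0
]	0
di	0
tri	0
tetra	0
penta	0
hexa	0
hepta	0
octa	0
nona	0
deca	0
undeca	0
dodeca	0
bis	0
tris	0
tetrakis	0
yl	0
ylidene	0
ylidyne	0
ene	0
diene	0
triene	0
yn	0
yne	0
ine	0
ane	0
an	0
in	0
o	0
a	0
e	0
oxa	0
aza	0
thia	0
spiro	0
cyclo	0
hydro	0
oph	0
N	0
O	0
S	0
H	0
ic	0
ate	0
ium	0
meth	1
eth	1
prop	1
but	1
pent	1
hex	1
hept	1
oct	1
non	1
dec	1
undec	1
dodec	1
chlor	1
brom	1
fluor	1
iod	1
amin	1
amid	1
imin	1
nitr	1
nitros	1
cyan	1
azid	1
az	1
hydroxy	1
oxo	1
ol	1
one	1
al	1
oic	1
carboxy	1
carbonyl	1
formyl	1
acetyl	1
benzoyl	1
oxy	1
peroxy	1
epoxy	1
thio	1
sulfanyl	1
sulfonyl	1
sulfin	1
mercapto	1
phosphor	1
phosphan	1
boran	1
silyl	1
stann	1
benz	1
benzo	1
phen	1
naphthal	1
anthracen	1
phenanthren	1
pyren	1
per	1
chrys	1
fluoranthen	1
acenaphthyl	1
azulen	1
inden	1
fluoren	1
triphenylen	1
pyrid	1
pyrimidin	1
pyrazin	1
pyridazin	1
quinolin	1
isoquinolin	1
quinoxalin	1
quinazolin	1
acridin	1
indol	1
isoindol	1
pyrrol	1
pyrrolidin	1
imidazol	1
pyrazol	1
triazol	1
tetrazol	1
oxazol	1
isoxazol	1
thiazol	1
isothiazol	1
furan	1
fur	1
thiophen	1
thi	1
purin	1
pterid	1
carbazol	1
phenazin	1
phenothiazin	1
cyclopent	1
cyclohex	1
cycloprop	1
cyclobut	1
styr	1
tolu	1
xyl	1
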