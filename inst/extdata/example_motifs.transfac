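AC M00001
XX
ID SYN$BHLH_01
XX
DE synthetic E-box-like helix-loop-helix motif (counts)
P0	A	C	G	T
01	1	2	1	1
02	2	1	1	1
03	0	4	0	1
04	5	0	0	0
05	0	5	0	0
06	0	0	5	0
07	0	1	0	4
08	0	0	5	0
09	1	0	3	1
10	1	1	2	1
XX
//
AC M00002
XX
ID SYN$GC_BOX_01
XX
DE synthetic GC-box-like motif (frequencies)
P0	A	C	G	T
01	0.10	0.20	0.60	0.10
02	0.05	0.05	0.85	0.05
03	0.05	0.05	0.85	0.05
04	0.10	0.40	0.40	0.10
05	0.05	0.05	0.85	0.05
06	0.05	0.85	0.05	0.05
07	0.10	0.60	0.20	0.10
08	0.05	0.05	0.85	0.05
XX
//
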