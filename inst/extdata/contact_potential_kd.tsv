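# Hydropathy-derived quasichemical-style residue-pair contact potential.
# Synthetic default: e(a,b) = -(2 * s(a) * s(b) + 0.6 * [a == b]), where s is
# the Kyte-Doolittle hydropathy index min-max scaled to [0,1] (Ile = 1,
# Arg = 0). Lower = more stabilizing; mutually hydrophobic burial and
# like-pair contacts are favourable, polar/charged mixed contacts near zero.
# Replaceable by any whitespace-delimited 20x20 matrix with one-letter
# header row and column.
aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-1.58	-1.089	-0.1556	-0.1556	-1.136	-0.6378	-0.2022	-1.4	-0.0933	-1.291	-0.9956	-0.1556	-0.4511	-0.1556	-0	-0.5756	-0.5911	-1.353	-0.56	-0.4978
C	-1.089	-1.81	-0.1728	-0.1728	-1.262	-0.7086	-0.2247	-1.556	-0.1037	-1.435	-1.106	-0.1728	-0.5012	-0.1728	-0	-0.6395	-0.6568	-1.504	-0.6222	-0.5531
D	-0.1556	-0.1728	-0.6247	-0.0247	-0.1802	-0.1012	-0.0321	-0.2222	-0.0148	-0.2049	-0.158	-0.0247	-0.0716	-0.0247	-0	-0.0914	-0.0938	-0.2148	-0.0889	-0.079
E	-0.1556	-0.1728	-0.0247	-0.6247	-0.1802	-0.1012	-0.0321	-0.2222	-0.0148	-0.2049	-0.158	-0.0247	-0.0716	-0.0247	-0	-0.0914	-0.0938	-0.2148	-0.0889	-0.079
F	-1.136	-1.262	-0.1802	-0.1802	-1.916	-0.739	-0.2343	-1.622	-0.1081	-1.496	-1.154	-0.1802	-0.5227	-0.1802	-0	-0.6669	-0.6849	-1.568	-0.6489	-0.5768
G	-0.6378	-0.7086	-0.1012	-0.1012	-0.739	-1.015	-0.1316	-0.9111	-0.0607	-0.8402	-0.6479	-0.1012	-0.2936	-0.1012	-0	-0.3746	-0.3847	-0.8807	-0.3644	-0.324
H	-0.2022	-0.2247	-0.0321	-0.0321	-0.2343	-0.1316	-0.6417	-0.2889	-0.0193	-0.2664	-0.2054	-0.0321	-0.0931	-0.0321	-0	-0.1188	-0.122	-0.2793	-0.1156	-0.1027
I	-1.4	-1.556	-0.2222	-0.2222	-1.622	-0.9111	-0.2889	-2.6	-0.1333	-1.844	-1.422	-0.2222	-0.6444	-0.2222	-0	-0.8222	-0.8444	-1.933	-0.8	-0.7111
K	-0.0933	-0.1037	-0.0148	-0.0148	-0.1081	-0.0607	-0.0193	-0.1333	-0.6089	-0.123	-0.0948	-0.0148	-0.043	-0.0148	-0	-0.0548	-0.0563	-0.1289	-0.0533	-0.0474
L	-1.291	-1.435	-0.2049	-0.2049	-1.496	-0.8402	-0.2664	-1.844	-0.123	-2.301	-1.312	-0.2049	-0.5943	-0.2049	-0	-0.7583	-0.7788	-1.783	-0.7378	-0.6558
M	-0.9956	-1.106	-0.158	-0.158	-1.154	-0.6479	-0.2054	-1.422	-0.0948	-1.312	-1.611	-0.158	-0.4583	-0.158	-0	-0.5847	-0.6005	-1.375	-0.5689	-0.5057
N	-0.1556	-0.1728	-0.0247	-0.0247	-0.1802	-0.1012	-0.0321	-0.2222	-0.0148	-0.2049	-0.158	-0.6247	-0.0716	-0.0247	-0	-0.0914	-0.0938	-0.2148	-0.0889	-0.079
P	-0.4511	-0.5012	-0.0716	-0.0716	-0.5227	-0.2936	-0.0931	-0.6444	-0.043	-0.5943	-0.4583	-0.0716	-0.8077	-0.0716	-0	-0.2649	-0.2721	-0.623	-0.2578	-0.2291
Q	-0.1556	-0.1728	-0.0247	-0.0247	-0.1802	-0.1012	-0.0321	-0.2222	-0.0148	-0.2049	-0.158	-0.0247	-0.0716	-0.6247	-0	-0.0914	-0.0938	-0.2148	-0.0889	-0.079
R	-0	-0	-0	-0	-0	-0	-0	-0	-0	-0	-0	-0	-0	-0	-0.6	-0	-0	-0	-0	-0
S	-0.5756	-0.6395	-0.0914	-0.0914	-0.6669	-0.3746	-0.1188	-0.8222	-0.0548	-0.7583	-0.5847	-0.0914	-0.2649	-0.0914	-0	-0.938	-0.3472	-0.7948	-0.3289	-0.2923
T	-0.5911	-0.6568	-0.0938	-0.0938	-0.6849	-0.3847	-0.122	-0.8444	-0.0563	-0.7788	-0.6005	-0.0938	-0.2721	-0.0938	-0	-0.3472	-0.9565	-0.8163	-0.3378	-0.3002
V	-1.353	-1.504	-0.2148	-0.2148	-1.568	-0.8807	-0.2793	-1.933	-0.1289	-1.783	-1.375	-0.2148	-0.623	-0.2148	-0	-0.7948	-0.8163	-2.469	-0.7733	-0.6874
W	-0.56	-0.6222	-0.0889	-0.0889	-0.6489	-0.3644	-0.1156	-0.8	-0.0533	-0.7378	-0.5689	-0.0889	-0.2578	-0.0889	-0	-0.3289	-0.3378	-0.7733	-0.92	-0.2844
Y	-0.4978	-0.5531	-0.079	-0.079	-0.5768	-0.324	-0.1027	-0.7111	-0.0474	-0.6558	-0.5057	-0.079	-0.2291	-0.079	-0	-0.2923	-0.3002	-0.6874	-0.2844	-0.8528
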