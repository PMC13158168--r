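# Al-27(n,alpha)Na-24 pointwise cross section, barns; threshold 3.4 MeV
# provenance: synthetic, ENDF-like shapes (see data-raw/make_nuclear_data.R)
energy_MeV,value
1e-20,0
1e-10,0
0.01,0
1,0
3.4,0
3.6,5e-04
4,0.006
4.5,0.015
5,0.031
5.5,0.05
6,0.071
6.5,0.086
7,0.098
7.5,0.106
8,0.112
8.5,0.117
9,0.12
9.5,0.121
10,0.121
11,0.118
12,0.111
13,0.1
14,0.085
15,0.07
17,0.055
20,0.042
25,0.03
30,0.023
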