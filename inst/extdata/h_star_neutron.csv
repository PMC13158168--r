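# Neutron fluence-to-ambient-dose-equivalent H*(10), pSv cm2 (ICRP 74; extended below 1e-9 and above 20 MeV)
# provenance: synthetic, ENDF-like shapes (see data-raw/make_nuclear_data.R)
energy_MeV,value
1e-20,6.6
1e-09,6.6
1e-08,9
2.53e-08,10.6
1e-07,12.9
2e-07,13.5
5e-07,13.6
1e-06,13.3
2e-06,12.9
5e-06,12
1e-05,11.3
2e-05,10.6
5e-05,9.9
1e-04,9.4
2e-04,8.9
5e-04,8.3
0.001,7.9
0.002,7.7
0.005,8
0.01,10.5
0.02,16.6
0.03,23.7
0.05,41.1
0.07,60
0.1,88
0.15,132
0.2,170
0.3,233
0.5,322
0.7,375
0.9,400
1,416
1.2,425
2,420
3,412
4,408
5,405
6,400
7,405
8,409
9,420
10,440
12,480
14,520
15,540
16,555
18,570
20,600
25,625
30,650
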