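# Mn-55(n,gamma)Mn-56 pointwise cross section, barns
# provenance: synthetic, ENDF-like shapes (see data-raw/make_nuclear_data.R)
energy_MeV,value
1e-20,21154900
1.7430746e-20,16023400
3.038309e-20,12136600
5.2959992e-20,9192590
9.2313215e-20,6962740
1.6090882e-19,5273780
2.8047607e-19,3994510
4.8889071e-19,3025560
8.5217297e-19,2291650
1.485401e-18,1735760
2.5891648e-18,1314720
4.5131073e-18,995805
7.8666826e-18,754251
1.3712215e-17,571292
2.3901413e-17,432713
4.1661945e-17,327750
7.2619877e-17,248247
1.2658186e-16,188030
2.2064162e-16,142419
3.8459481e-16,107873
6.7037743e-16,81705.8
1.1685179e-15,61886.4
2.0368138e-15,46874.6
3.5503183e-15,35504.2
6.1884696e-15,26892
1.0786964e-14,20368.8
1.8802483e-14,15428
3.277413e-14,11685.6
5.7127752e-14,8851.07
9.9577933e-14,6704.1
1.7357176e-13,5077.91
3.0254853e-13,3846.2
5.2736465e-13,2913.26
9.1923591e-13,2206.62
1.6022967e-12,1671.4
2.7929227e-12,1266
4.8682726e-12,958.944
8.4857622e-12,726.369
1.4791316e-11,550.21
2.5782368e-11,416.782
4.494059e-11,315.72
7.8334799e-11,239.172
1.365434e-10,181.193
2.3800532e-10,137.278
4.1486103e-10,104.015
7.2313372e-10,78.8208
1.260476e-09,59.7381
2.1971037e-09,45.2842
3.8297156e-09,34.3365
6.6754798e-09,26.0443
1.1635859e-08,19.7636
2.028217e-08,15.0064
3.5353336e-08,11.4032
6.1623501e-08,8.674
1.0741436e-07,6.60687
1.8723124e-07,5.0412
3.2635801e-07,3.85538
5.6886635e-07,2.95734
9.9157647e-07,2.27734
1.7283917e-06,1.76267
3.0127157e-06,1.3735
5.2513881e-06,1.07991
7e-06,0.957965
9.1535612e-06,0.859654
1.595534e-05,0.696775
2.7811347e-05,0.581122
4e-05,0.52927
4.8477252e-05,0.510038
7.3e-05,0.493234
8.4499466e-05,0.498331
0.000106,0.525217
0.000139,0.613203
0.00014728887,0.646417
0.000172,0.783774
0.000205,1.11627
0.000238,1.84744
0.00025673549,2.71601
0.000271,3.91529
0.000304,14.1243
0.000337,140.118
0.00037,14.113
0.000403,3.89216
0.000436,1.81163
0.0004475091,1.47652
0.000469,1.0662
0.000502,0.716888
0.000535,0.52523
0.000568,0.408506
0.000601,0.331927
0.000634,0.278798
0.000667,0.240295
7e-04,0.211399
0.000733,0.189079
0.000766,0.17142
0.00078004174,0.164994
0.000799,0.157161
0.000832,0.145443
0.000865,0.135666
0.000898,0.1274
0.000931,0.120327
0.000964,0.114212
0.000997,0.108876
0.0013596709,0.0765667
0.0023700078,0.0505532
0.0041311004,0.0370906
0.0072008161,0.0282895
0.012551559,0.0219962
0.021878304,0.0173388
0.038135516,0.0138448
0.066473048,0.0112091
0.11586748,0.00921613
0.20196566,0.00770773
0.35204121,0.00656559
0.61363408,0.00570063
1.06961,0.00504551
1.8644099,0.00454933
3.2498056,0.0041735
5.6646535,0.00388884
9.8739135,0.00367324
17.210968,0.00350993
30,0.00338623
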