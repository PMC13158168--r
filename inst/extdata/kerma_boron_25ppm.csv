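# Boron dose coefficient at 25 ppm 10B, Gy cm2 per unit fluence
# provenance: synthetic, ENDF-like shapes (see data-raw/make_nuclear_data.R)
energy_MeV,value
1e-20,3.42567e-06
2.0476825e-20,2.39394e-06
4.1930038e-20,1.67295e-06
8.5859406e-20,1.1691e-06
1.7581281e-19,8.16996e-07
3.6000881e-19,5.70937e-07
7.3718376e-19,3.98986e-07
1.5095183e-18,2.78821e-07
3.0910143e-18,1.94847e-07
6.329416e-18,1.36164e-07
1.2960635e-17,9.51551e-08
2.6539265e-17,6.64968e-08
5.434399e-17,4.64696e-08
1.1127924e-16,3.24742e-08
2.2786456e-16,2.26938e-08
4.6659427e-16,1.5859e-08
9.5543694e-16,1.10827e-08
1.9564315e-15,7.74485e-09
4.0061507e-15,5.41229e-09
8.2033249e-15,3.78225e-09
1.6797805e-14,2.64313e-09
3.4396572e-14,1.84709e-09
7.043326e-14,1.29079e-09
1.4422496e-13,9.02038e-10
2.9532693e-13,6.30367e-10
6.0473579e-13,4.40517e-10
1.2383069e-12,3.07844e-10
2.5356595e-12,2.15129e-10
5.1922256e-12,1.50338e-10
1.063203e-11,1.0506e-10
2.1771021e-11,7.34185e-11
4.4580141e-11,5.13067e-11
9.1285975e-11,3.58544e-11
1.869247e-10,2.5056e-11
3.8276244e-10,1.75098e-11
7.8377596e-10,1.22363e-11
1.6049244e-09,8.55102e-12
3.2863756e-09,5.97567e-12
6.7294539e-09,4.17595e-12
1.3779785e-08,2.91826e-12
2.8216626e-08,2.03935e-12
5.7778691e-08,1.42515e-12
1.1831242e-07,9.95933e-13
2.4226627e-07,6.95983e-13
4.9608441e-07,4.86371e-13
1.0158234e-06,3.39888e-13
2.0800838e-06,2.37522e-13
4.2593513e-06,1.65987e-13
8.7217993e-06,1.15996e-13
1.7859476e-05,8.10608e-14
3.6570538e-05,5.66473e-14
7.4884851e-05,3.95866e-14
0.0001533404,2.76641e-14
0.00031399246,1.93324e-14
0.00064295689,1.351e-14
0.0013165716,9.44111e-15
0.0026959206,6.59768e-15
0.0055203896,4.61063e-15
0.011304005,3.22202e-15
0.023147015,2.25163e-15
0.047397738,1.5735e-15
0.09705552,1.0996e-15
0.19873889,7.68429e-16
0.40695416,5.36998e-16
0.83331293,3.75268e-16
1.7063603,2.62246e-16
3.4940843,1.83265e-16
7.1547753,1.2807e-16
14.650709,8.94985e-17
30,6.25438e-17
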