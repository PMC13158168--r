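# Nitrogen 14N(n,p)14C dose coefficient in ICRU soft tissue, Gy cm2
# provenance: synthetic, ENDF-like shapes (see data-raw/make_nuclear_data.R)
energy_MeV,value
1e-20,3.23308e-07
2.0476825e-20,2.25936e-07
4.1930038e-20,1.5789e-07
8.5859406e-20,1.10337e-07
1.7581281e-19,7.71066e-08
3.6000881e-19,5.3884e-08
7.3718376e-19,3.76555e-08
1.5095183e-18,2.63146e-08
3.0910143e-18,1.83893e-08
6.329416e-18,1.28509e-08
1.2960635e-17,8.98056e-09
2.6539265e-17,6.27584e-09
5.434399e-17,4.38572e-09
1.1127924e-16,3.06485e-09
2.2786456e-16,2.1418e-09
4.6659427e-16,1.49674e-09
9.5543694e-16,1.04596e-09
1.9564315e-15,7.30944e-10
4.0061507e-15,5.10802e-10
8.2033249e-15,3.56962e-10
1.6797805e-14,2.49454e-10
3.4396572e-14,1.74325e-10
7.043326e-14,1.21823e-10
1.4422496e-13,8.51327e-11
2.9532693e-13,5.94929e-11
6.0473579e-13,4.15751e-11
1.2383069e-12,2.90538e-11
2.5356595e-12,2.03035e-11
5.1922256e-12,1.41886e-11
1.063203e-11,9.91536e-12
2.1771021e-11,6.92911e-12
4.4580141e-11,4.84224e-12
9.1285975e-11,3.38388e-12
1.869247e-10,2.36474e-12
3.8276244e-10,1.65254e-12
7.8377596e-10,1.15484e-12
1.6049244e-09,8.07029e-13
3.2863756e-09,5.63973e-13
6.7294539e-09,3.94118e-13
1.3779785e-08,2.7542e-13
2.8216626e-08,1.9247e-13
5.7778691e-08,1.34503e-13
1.1831242e-07,9.39943e-14
2.4226627e-07,6.56856e-14
4.9608441e-07,4.59028e-14
1.0158234e-06,3.2078e-14
2.0800838e-06,2.24169e-14
4.2593513e-06,1.56655e-14
8.7217993e-06,1.09475e-14
1.7859476e-05,7.65037e-15
3.6570538e-05,5.34627e-15
7.4884851e-05,3.73611e-15
0.0001533404,2.61089e-15
0.00031399246,1.82456e-15
0.00064295689,1.27505e-15
0.0013165716,8.91034e-16
0.0026959206,6.22677e-16
0.0055203896,4.35143e-16
0.011304005,3.04089e-16
0.023147015,2.12505e-16
0.047397738,1.48504e-16
0.09705552,1.03778e-16
0.19873889,7.25229e-17
0.40695416,5.06808e-17
0.83331293,3.54171e-17
1.7063603,2.47503e-17
3.4940843,1.72962e-17
7.1547753,1.2087e-17
14.650709,8.4467e-18
30,5.90277e-18
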