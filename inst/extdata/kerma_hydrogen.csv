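# Hydrogen elastic-recoil dose coefficient in ICRU soft tissue, Gy cm2
# provenance: synthetic, ENDF-like shapes (see data-raw/make_nuclear_data.R)
energy_MeV,value
1e-20,9.86103e-31
2.0476825e-20,2.01923e-30
4.1930038e-20,4.13473e-30
8.5859406e-20,8.46662e-30
1.7581281e-19,1.7337e-29
3.6000881e-19,3.55006e-29
7.3718376e-19,7.26939e-29
1.5095183e-18,1.48854e-28
3.0910143e-18,3.04806e-28
6.329416e-18,6.24146e-28
1.2960635e-17,1.27805e-27
2.6539265e-17,2.61705e-27
5.434399e-17,5.35888e-27
1.1127924e-16,1.09733e-26
2.2786456e-16,2.24698e-26
4.6659427e-16,4.6011e-26
9.5543694e-16,9.42159e-26
1.9564315e-15,1.92924e-25
4.0061507e-15,3.95048e-25
8.2033249e-15,8.08932e-25
1.6797805e-14,1.65644e-24
3.4396572e-14,3.39186e-24
7.043326e-14,6.94545e-24
1.4422496e-13,1.42221e-23
2.9532693e-13,2.91223e-23
6.0473579e-13,5.96332e-23
1.2383069e-12,1.2211e-22
2.5356595e-12,2.50042e-22
5.1922256e-12,5.12007e-22
1.063203e-11,1.04843e-21
2.1771021e-11,2.14685e-21
4.4580141e-11,4.39606e-21
9.1285975e-11,9.00174e-21
1.869247e-10,1.84327e-20
3.8276244e-10,3.77443e-20
7.8377596e-10,7.72884e-20
1.6049244e-09,1.58262e-19
3.2863756e-09,3.2407e-19
6.7294539e-09,6.63593e-19
1.3779785e-08,1.35883e-18
2.8216626e-08,2.78245e-18
5.7778691e-08,5.69757e-18
1.1831242e-07,1.16668e-17
2.4226627e-07,2.38899e-17
4.9608441e-07,4.89187e-17
1.0158234e-06,1.00169e-16
2.0800838e-06,2.05112e-16
4.2593513e-06,4.19994e-16
8.7217993e-06,8.59966e-16
1.7859476e-05,1.76074e-15
3.6570538e-05,3.60458e-15
7.4884851e-05,7.37752e-15
0.0001533404,1.5092e-14
0.00031399246,3.08421e-14
0.00064295689,6.28987e-14
0.0013165716,1.27742e-13
0.0026959206,2.57316e-13
0.0055203896,5.10292e-13
0.011304005,9.84258e-13
0.023147015,1.81665e-12
0.047397738,3.16199e-12
0.09705552,5.1704e-12
0.19873889,8.02183e-12
0.40695416,1.20051e-11
0.83331293,1.75863e-11
1.7063603,2.54657e-11
3.4940843,3.66562e-11
7.1547753,5.26065e-11
14.650709,7.53858e-11
30,1.0795e-10
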