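# Au-197(n,gamma)Au-198 pointwise cross section, barns
# provenance: synthetic, ENDF-like shapes (see data-raw/make_nuclear_data.R)
energy_MeV,value
1e-20,156912000
1.7430746e-20,118850000
3.038309e-20,90020500
5.2959992e-20,68184200
9.2313215e-20,51644700
1.6090882e-19,39117200
2.8047607e-19,29628500
4.8889071e-19,22441500
8.5217297e-19,16997800
1.485401e-18,12874700
2.5891648e-18,9751640
4.5131073e-18,7386180
7.8666826e-18,5594510
1.3712215e-17,4237450
2.3901413e-17,3209570
4.1661945e-17,2431020
7.2619877e-17,1841330
1.2658186e-16,1394680
2.2064162e-16,1056370
3.8459481e-16,800127
6.7037743e-16,606041
1.1685179e-15,459035
2.0368138e-15,347688
3.5503183e-15,263350
6.1884696e-15,199471
1.0786964e-14,151086
1.8802483e-14,114439
3.277413e-14,86680.8
5.7127752e-14,65656.1
9.9577933e-14,49731.3
1.7357176e-13,37669.5
3.0254853e-13,28533.4
5.2736465e-13,21613.6
9.1923591e-13,16372.3
1.6022967e-12,12402.3
2.7929227e-12,9395.39
4.8682726e-12,7117.84
8.4857622e-12,5392.77
1.4791316e-11,4086.14
2.5782368e-11,3096.47
4.494059e-11,2346.86
7.8334799e-11,1779.08
1.365434e-10,1349.03
2.3800532e-10,1023.3
4.1486103e-10,776.584
7.2313372e-10,589.713
1.260476e-09,448.172
2.1971037e-09,340.966
3.8297156e-09,259.767
6.6754798e-09,198.269
1.1635859e-08,151.695
2.028217e-08,116.432
3.5353336e-08,89.7435
6.1623501e-08,69.5678
1.0741436e-07,54.3555
1.8723124e-07,42.9605
3.2635801e-07,34.5727
5.6886635e-07,28.7186
7e-07,27.1656
9.1e-07,25.7597
9.9157647e-07,25.4577
1.12e-06,25.1914
1.33e-06,25.2156
1.54e-06,25.7395
1.7283917e-06,26.6219
1.75e-06,26.749
1.96e-06,28.2852
2.17e-06,30.4428
2.38e-06,33.3814
2.59e-06,37.353
2.8e-06,42.7536
3.01e-06,50.2202
3.0127157e-06,50.3343
3.22e-06,60.8175
3.43e-06,76.4258
3.64e-06,100.612
3.85e-06,140.82
4.06e-06,214.764
4.27e-06,373.527
4.48e-06,818.304
4.69e-06,3007.33
4.9e-06,30007.2
5.11e-06,3007.02
5.2513881e-06,1152.02
5.32e-06,817.694
5.53e-06,372.606
5.74e-06,213.526
5.95e-06,139.256
6.16e-06,98.7099
6.37e-06,74.1704
6.58e-06,58.1902
6.79e-06,47.1976
7e-06,39.3071
7.21e-06,33.4467
7.42e-06,28.9707
7.63e-06,25.4715
7.84e-06,22.6812
8.05e-06,20.4179
8.26e-06,18.5549
8.47e-06,17.0012
8.68e-06,15.6905
8.89e-06,14.5734
9.1e-06,13.6126
9.1535612e-06,13.3889
1.595534e-05,5.21099
2.7811347e-05,3.33544
4.8477252e-05,2.41107
8.4499466e-05,1.81019
0.00014728887,1.38017
0.00025673549,1.06161
0.0004475091,0.822498
0.00078004174,0.642066
0.0013596709,0.50562
0.0023700078,0.402343
0.0041311004,0.324141
0.0072008161,0.264915
0.012551559,0.220059
0.021878304,0.186084
0.038135516,0.160351
0.066473048,0.14086
0.11586748,0.126097
0.20196566,0.114916
0.35204121,0.106446
0.61363408,0.100031
1.06961,0.0951721
1.8644099,0.0914918
3.2498056,0.0887042
5.6646535,0.0865928
9.8739135,0.0849936
17.210968,0.0837823
30,0.0828648
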