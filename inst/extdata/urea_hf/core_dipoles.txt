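# <core MO | r | occupied MO>, 4 cores x n_occ rows, x y z
-3.41165966e-02 5.12925669e-02 -3.23532942e+00
6.98500507e-06 4.39171656e-07 -9.98956605e-06
6.52965126e-06 -1.24217491e-09 1.07716016e-05
2.06743347e-06 -5.33057803e-06 2.84317372e-04
1.07800371e-04 -2.66173973e-04 1.43792234e-02
-6.83185515e-05 1.06306392e-04 -5.37230854e-03
3.35926300e-03 6.33379616e-05 -6.12840450e-05
1.90042393e-04 -1.72688418e-04 8.44756189e-03
1.60181439e-02 2.76526044e-03 -2.85629199e-04
-1.84536250e-04 1.72611952e-04 -1.48115570e-02
-8.00838890e-03 -1.36228715e-03 2.70264351e-05
-6.60610513e-04 1.97850300e-03 -4.51161790e-02
-7.97421301e-03 2.81380369e-02 2.38154813e-03
-4.89283387e-02 -1.96953907e-02 -2.98590919e-05
-7.42112456e-04 9.97019608e-04 3.73627640e-03
2.16269840e-02 -3.71659550e-02 -7.05723892e-04
6.98500507e-06 4.39171656e-07 -9.98956605e-06
-2.16986565e+00 -1.44828894e-01 4.63838460e-01
1.78565728e-01 1.06809338e-02 -1.53255405e-03
2.39876787e-04 1.70491626e-05 -1.46407105e-04
4.18300244e-03 1.36497975e-03 -3.50907352e-03
5.01549094e-03 3.62654512e-03 -2.55851666e-04
4.47916949e-04 -4.15314460e-03 2.42246657e-03
3.19407444e-02 -4.46314521e-03 -1.07315870e-02
-1.06668445e-02 7.55821256e-03 3.43090482e-02
1.76920966e-02 3.24758722e-03 2.95348891e-02
3.48383914e-02 -3.41007301e-04 1.47765740e-02
4.45572059e-03 -3.88423063e-03 -1.64089510e-02
2.07510362e-03 2.58833153e-02 -5.05442819e-03
-1.10680175e-02 8.92240769e-03 1.13145174e-02
-2.92770642e-03 -4.67118142e-02 6.71348117e-03
5.38288970e-03 2.56102059e-02 -9.87461048e-03
6.52965126e-06 -1.24217491e-09 1.07716016e-05
1.78565728e-01 1.06809338e-02 -1.53255405e-03
2.16464347e+00 1.14438688e-01 4.26693984e-01
2.22479729e-04 1.09084318e-05 1.53590537e-04
3.88371765e-03 1.07699224e-03 3.77297434e-03
4.47004387e-03 3.10726912e-03 2.30225818e-04
-5.43272446e-04 4.29923879e-03 2.34410505e-03
2.98854537e-02 -4.18621094e-03 1.14730149e-02
1.19556181e-02 -9.39153838e-03 3.07287952e-02
1.50803603e-02 4.73427091e-03 -3.22286848e-02
-3.77555056e-02 -1.32920484e-03 1.47178743e-02
4.49322911e-03 -6.29032881e-03 1.66976108e-02
-2.13051575e-03 -2.72396015e-02 -7.18145409e-03
1.23533759e-02 -9.66292614e-03 9.83745981e-03
-1.40108515e-03 -4.14017418e-02 -8.73758597e-03
-5.79271738e-03 -3.01337163e-02 -1.05928852e-02
2.06743347e-06 -5.33057803e-06 2.84317372e-04
2.39876787e-04 1.70491626e-05 -1.46407105e-04
2.22479729e-04 1.09084318e-05 1.53590537e-04
-1.75312094e-02 8.57387753e-03 -9.63572621e-01
-1.71371936e-04 4.09293427e-04 -2.04915482e-02
-6.51490583e-05 -6.02037906e-04 3.39960099e-02
2.77966476e-02 4.59114253e-04 4.09050146e-05
6.04496111e-04 -4.28092282e-04 2.16668462e-02
4.05418648e-02 7.45693223e-03 -2.97163092e-04
-1.16553866e-04 -4.65816657e-04 1.21654591e-02
-2.95158481e-02 -3.15347159e-03 1.78317572e-04
-9.23924121e-05 8.89181109e-04 4.35645562e-02
-9.97984869e-03 4.25209316e-02 -7.74267419e-04
5.23242808e-03 -7.65137351e-03 -2.11974978e-04
3.12942317e-04 4.36721798e-04 -6.07950506e-03
-6.23765159e-03 -7.82941344e-03 -2.26645475e-04
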