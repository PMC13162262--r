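temperature,salinity,ph,alkalinity,dic,dh_ddic,dh_ddic2alk
15,35,7.7,2300,2219.054820,1.35532551e-04,1.30521751e-04
15,35,7.7,2650,2562.584862,1.21249402e-04,1.16766667e-04
15,35,8,2300,2100.712738,4.95229893e-05,4.38668164e-05
15,35,8,2650,2430.725450,4.45165861e-05,3.94322099e-05
15,35,8.1,2300,2051.325061,3.49211664e-05,2.98246950e-05
15,35,8.1,2650,2375.785179,3.13892481e-05,2.68082326e-05
15,38,7.7,2300,2208.558335,1.29282615e-04,1.23823312e-04
15,38,7.7,2650,2551.168493,1.15866775e-04,1.10973991e-04
15,38,8,2300,2083.827395,4.69110205e-05,4.11719016e-05
15,38,8,2650,2412.417803,4.22310307e-05,3.70644642e-05
15,38,8.1,2300,2031.729510,3.31379990e-05,2.79903895e-05
15,38,8.1,2650,2354.545259,2.98275627e-05,2.51941917e-05
25,35,7.7,2300,2166.894063,1.14035260e-04,1.05769119e-04
25,35,7.7,2650,2504.208735,1.02176603e-04,9.47700679e-05
25,35,8,2300,2023.277177,4.06925203e-05,3.39262896e-05
25,35,8,2650,2344.178700,3.65341325e-05,3.04593460e-05
25,35,8.1,2300,1963.492843,2.90346968e-05,2.30752690e-05
25,35,8.1,2650,2277.573754,2.60534738e-05,2.07059478e-05
25,38,7.7,2300,2153.483999,1.08350203e-04,9.97667550e-05
25,38,7.7,2650,2489.620588,9.72410044e-05,8.95376215e-05
25,38,8,2300,2002.219780,3.87157436e-05,3.18790588e-05
25,38,8,2650,2321.317110,3.48061051e-05,2.86598104e-05
25,38,8.1,2300,1939.498348,2.77304462e-05,2.17141690e-05
25,38,8.1,2650,2251.531108,2.49147271e-05,1.95093361e-05
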