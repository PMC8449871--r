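sample,yield_pa,ads_um,lds_um,ads_pressure_pa,lds_pressure_pa,ci_ads,ci_lds
8,3.01e-01,12.49,34.234,4.03e-04,1.11e-03,747,270
10,2.35e+00,11.67,34.25,3.80e-04,1.12e-03,6183,2107
11,2.96e-01,15.63,58.75,5.09e-04,1.91e-03,581,155
18,2.28e+00,13.79,33.89,4.49e-04,1.10e-03,5076,2066
24,4.74e+00,11.27,20,3.67e-04,6.51e-04,12914,7277
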