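# illuminant: woodland_shade
# provenance: synthetic woodland-shade irradiance: blue-grey skylight-dominated spectrum, Planck photon spectrum at 9000 K
# units: relative photon flux (unit peak); wavelength in nm
# note: synthetic stand-in generated by a parametric model, not a measured irradiance table
wavelength,irradiance
300,0.82217
305,0.840195
310,0.85714
315,0.873014
320,0.887826
325,0.901593
330,0.914331
335,0.926062
340,0.93681
345,0.946599
350,0.955457
355,0.963412
360,0.970494
365,0.976732
370,0.982157
375,0.9868
380,0.990693
385,0.993866
390,0.99635
395,0.998175
400,0.999372
405,0.999971
410,1
415,0.999488
420,0.998462
425,0.99695
430,0.994978
435,0.992571
440,0.989753
445,0.986549
450,0.982981
455,0.979072
460,0.974843
465,0.970313
470,0.965503
475,0.960432
480,0.955116
485,0.949575
490,0.943824
495,0.937878
500,0.931754
505,0.925464
510,0.919023
515,0.912444
520,0.90574
525,0.89892
530,0.891998
535,0.884983
540,0.877886
545,0.870716
550,0.863482
555,0.856192
560,0.848855
565,0.841478
570,0.834069
575,0.826634
580,0.819179
585,0.811711
590,0.804235
595,0.796757
600,0.789281
605,0.781813
610,0.774357
615,0.766916
620,0.759495
625,0.752098
630,0.744727
635,0.737386
640,0.730079
645,0.722806
650,0.715572
655,0.708379
660,0.701228
665,0.694122
670,0.687062
675,0.680051
680,0.673089
685,0.666179
690,0.659322
695,0.652518
700,0.645769
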