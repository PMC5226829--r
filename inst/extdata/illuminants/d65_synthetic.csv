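# illuminant: d65
# provenance: synthetic approximation of CIE D65 daylight: Planck photon spectrum at 6504 K
# units: relative photon flux (unit peak); wavelength in nm
# note: synthetic stand-in generated by a parametric model, not a measured irradiance table
wavelength,irradiance
300,0.38833
305,0.410224
310,0.432133
315,0.454
320,0.475772
325,0.497397
330,0.518827
335,0.540018
340,0.560927
345,0.581516
350,0.601751
355,0.621598
360,0.641029
365,0.660019
370,0.678542
375,0.696581
380,0.714116
385,0.731132
390,0.747617
395,0.763561
400,0.778954
405,0.793791
410,0.808068
415,0.82178
420,0.834928
425,0.847512
430,0.859534
435,0.870996
440,0.881903
445,0.892261
450,0.902075
455,0.911352
460,0.920101
465,0.928329
470,0.936047
475,0.943263
480,0.949988
485,0.956232
490,0.962006
495,0.96732
500,0.972188
505,0.976619
510,0.980625
515,0.984218
520,0.98741
525,0.990213
530,0.992638
535,0.994696
540,0.9964
545,0.997761
550,0.99879
555,0.999499
560,0.999899
565,1
570,0.999814
575,0.99935
580,0.99862
585,0.997634
590,0.996401
595,0.994932
600,0.993235
605,0.991321
610,0.989198
615,0.986875
620,0.984361
625,0.981664
630,0.978793
635,0.975754
640,0.972557
645,0.969209
650,0.965716
655,0.962086
660,0.958326
665,0.954442
670,0.950442
675,0.94633
680,0.942113
685,0.937797
690,0.933388
695,0.92889
700,0.92431
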