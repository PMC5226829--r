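# illuminant: cloudy_sky
# provenance: synthetic cloudy-sky irradiance: Planck photon spectrum at 6800 K (spectrally flattened daylight)
# units: relative photon flux (unit peak); wavelength in nm
# note: synthetic stand-in generated by a parametric model, not a measured irradiance table
wavelength,irradiance
300,0.570129
305,0.590276
310,0.610004
315,0.629289
320,0.648108
325,0.666442
330,0.684277
335,0.701598
340,0.718395
345,0.734661
350,0.750387
355,0.765571
360,0.780211
365,0.794304
370,0.807853
375,0.82086
380,0.833328
385,0.845261
390,0.856666
395,0.867548
400,0.877916
405,0.887777
410,0.897141
415,0.906015
420,0.91441
425,0.922336
430,0.929804
435,0.936823
440,0.943404
445,0.949559
450,0.955299
455,0.960634
460,0.965577
465,0.970137
470,0.974326
475,0.978156
480,0.981637
485,0.984779
490,0.987595
495,0.990094
500,0.992287
505,0.994184
510,0.995795
515,0.99713
520,0.998199
525,0.999011
530,0.999576
535,0.999903
540,1
545,0.999877
550,0.999541
555,0.999001
560,0.998265
565,0.997341
570,0.996236
575,0.994958
580,0.993513
585,0.99191
590,0.990154
595,0.988252
600,0.98621
605,0.984035
610,0.981732
615,0.979307
620,0.976766
625,0.974115
630,0.971358
635,0.9685
640,0.965546
645,0.962502
650,0.95937
655,0.956157
660,0.952866
665,0.949502
670,0.946067
675,0.942566
680,0.939003
685,0.935382
690,0.931705
695,0.927975
700,0.924197
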