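# illuminant: woodland_gaps
# provenance: synthetic woodland-gap irradiance: reddish direct sunlight, Planck photon spectrum at 5000 K
# units: relative photon flux (unit peak); wavelength in nm
# note: synthetic stand-in generated by a parametric model, not a measured irradiance table
wavelength,irradiance
300,0.121431
305,0.133018
310,0.14513
315,0.157746
320,0.170843
325,0.184397
330,0.198382
335,0.212771
340,0.227535
345,0.242644
350,0.258069
355,0.273778
360,0.289742
365,0.30593
370,0.32231
375,0.338853
380,0.355527
385,0.372305
390,0.389156
395,0.406053
400,0.422968
405,0.439876
410,0.456749
415,0.473565
420,0.490299
425,0.506929
430,0.523434
435,0.539794
440,0.55599
445,0.572004
450,0.587819
455,0.603419
460,0.618791
465,0.63392
470,0.648794
475,0.663402
480,0.677733
485,0.691779
490,0.70553
495,0.718979
500,0.732119
505,0.744945
510,0.757451
515,0.769634
520,0.781489
525,0.793015
530,0.804208
535,0.815067
540,0.825591
545,0.835781
550,0.845635
555,0.855155
560,0.864342
565,0.873198
570,0.881723
575,0.889921
580,0.897794
585,0.905345
590,0.912577
595,0.919494
600,0.9261
605,0.932399
610,0.938394
615,0.944091
620,0.949493
625,0.954605
630,0.959433
635,0.963981
640,0.968254
645,0.972258
650,0.975997
655,0.979476
660,0.982702
665,0.985678
670,0.988412
675,0.990907
680,0.99317
685,0.995205
690,0.997018
695,0.998615
700,1
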