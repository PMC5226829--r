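# illuminant: forest_shade
# provenance: synthetic forest-shade irradiance: daylight (6504 K) filtered by foliage transmission (yellow-green rich; Gaussian band at 550 nm over a 15% broadband floor)
# units: relative photon flux (unit peak); wavelength in nm
# note: synthetic stand-in generated by a parametric model, not a measured irradiance table
wavelength,irradiance
300,0.0507131
305,0.0535723
310,0.0564335
315,0.0592892
320,0.0621326
325,0.0649568
330,0.0677557
335,0.0705236
340,0.0732553
345,0.0759461
350,0.0785921
355,0.0811902
360,0.0837384
365,0.0862364
370,0.0886856
375,0.0910909
380,0.0934612
385,0.0958113
390,0.0981645
395,0.100556
400,0.103035
405,0.105673
410,0.108567
415,0.111847
420,0.115684
425,0.120295
430,0.125955
435,0.132995
440,0.14181
445,0.152855
450,0.166636
455,0.183695
460,0.204589
465,0.229857
470,0.259977
475,0.295321
480,0.336104
485,0.38233
490,0.433745
495,0.489796
500,0.549614
505,0.612004
510,0.67547
515,0.738263
520,0.798451
525,0.854014
530,0.902959
535,0.943432
540,0.973842
545,0.992958
550,1
555,0.994688
560,0.977261
565,0.948463
570,0.909487
575,0.861895
580,0.807516
585,0.748326
590,0.686337
595,0.62348
600,0.561513
605,0.501949
610,0.446005
615,0.394582
620,0.348265
625,0.307344
630,0.271849
635,0.241599
640,0.216253
645,0.195357
650,0.178392
655,0.164817
660,0.154099
665,0.145737
670,0.139276
675,0.134322
680,0.130535
685,0.127638
690,0.125404
695,0.123658
700,0.122262
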