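# illuminant: blue_sky
# provenance: synthetic blue-sky irradiance: Planck photon spectrum at 6504 K weighted by Rayleigh scattering (lambda^-4), renormalized
# units: relative photon flux (unit peak); wavelength in nm
# note: synthetic stand-in generated by a parametric model, not a measured irradiance table
wavelength,irradiance
300,1
305,0.988794
310,0.976011
315,0.96183
320,0.946419
325,0.929938
330,0.912538
335,0.894361
340,0.875537
345,0.856189
350,0.836428
355,0.816358
360,0.796072
365,0.775656
370,0.755187
375,0.734735
380,0.714362
385,0.694124
390,0.67407
395,0.654244
400,0.634682
405,0.615418
410,0.596481
415,0.577893
420,0.559675
425,0.541844
430,0.524413
435,0.507392
440,0.490789
445,0.474609
450,0.458856
455,0.443532
460,0.428636
465,0.414166
470,0.40012
475,0.386494
480,0.373282
485,0.360479
490,0.348079
495,0.336073
500,0.324455
505,0.313216
510,0.302348
515,0.291841
520,0.281688
525,0.271879
530,0.262405
535,0.253256
540,0.244423
545,0.235898
550,0.227671
555,0.219733
560,0.212074
565,0.204687
570,0.197562
575,0.190691
580,0.184066
585,0.177677
590,0.171518
595,0.165581
600,0.159857
605,0.154339
610,0.149021
615,0.143895
620,0.138954
625,0.134192
630,0.129602
635,0.125179
640,0.120915
645,0.116805
650,0.112844
655,0.109027
660,0.105347
665,0.1018
670,0.0983808
675,0.0950849
680,0.0919076
685,0.0888446
690,0.0858915
695,0.0830442
700,0.0802989
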