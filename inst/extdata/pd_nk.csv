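wavelength_nm,n,k
300,1.1454,2.263
310,1.15,2.3267
320,1.1576,2.3925
330,1.1681,2.4594
340,1.1811,2.5267
350,1.1962,2.5939
360,1.2132,2.6607
370,1.2316,2.7268
380,1.2513,2.7922
390,1.2721,2.8568
400,1.2936,2.9204
410,1.3158,2.9831
420,1.3385,3.0449
430,1.3616,3.1057
440,1.3849,3.1657
450,1.4085,3.2248
460,1.4322,3.2831
470,1.4559,3.3406
480,1.4797,3.3973
490,1.5034,3.4533
500,1.527,3.5085
510,1.5506,3.5632
520,1.574,3.6172
530,1.5972,3.6706
540,1.6202,3.7234
550,1.6431,3.7757
560,1.6658,3.8275
570,1.6882,3.8788
580,1.7104,3.9296
590,1.7324,3.98
600,1.7541,4.03
610,1.7755,4.0796
620,1.7968,4.1288
630,1.8177,4.1777
640,1.8385,4.2263
650,1.8589,4.2745
660,1.8792,4.3225
670,1.8991,4.3702
680,1.9188,4.4176
690,1.9383,4.4648
700,1.9575,4.5117
710,1.9765,4.5584
720,1.9953,4.605
730,2.0138,4.6513
740,2.032,4.6974
750,2.0501,4.7434
760,2.0679,4.7892
770,2.0855,4.8349
780,2.103,4.8804
790,2.1202,4.9258
800,2.1371,4.971
810,2.1539,5.0162
820,2.1706,5.0612
830,2.187,5.1062
840,2.2032,5.151
850,2.2193,5.1958
860,2.2352,5.2405
870,2.2509,5.2851
880,2.2664,5.3296
890,2.2819,5.3741
900,2.2971,5.4185
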