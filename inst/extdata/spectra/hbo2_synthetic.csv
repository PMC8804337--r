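# oxyhemoglobin (HbO2) specific absorption per uM tetramer
# synthetic reconstruction: smooth spline through canonical spectral landmarks,
# not a digitized literature table; internally consistent across this package
# unit_tag: specific-absorption mm^-1.uM^-1
wavelength_nm,value
450,0.0145063
452,0.0134973
454,0.0125642
456,0.0117061
458,0.0109214
460,0.0102076
462,0.00956197
464,0.00898141
466,0.00846272
468,0.00800277
470,0.00759853
472,0.00724623
474,0.00693861
476,0.00666859
478,0.0064301
480,0.00621796
482,0.00602764
484,0.00585514
486,0.00569694
488,0.00554987
490,0.00541107
492,0.00527881
494,0.00515482
496,0.00504147
498,0.00494094
500,0.00485526
502,0.0047864
504,0.00473632
506,0.00470706
508,0.00470088
510,0.0047203
512,0.00476889
514,0.00485319
516,0.00498148
518,0.0051638
520,0.00541276
522,0.00574466
524,0.0061811
526,0.00675008
528,0.00746187
530,0.00829656
532,0.00921735
534,0.0101653
536,0.0110556
538,0.0117798
540,0.0122163
542,0.0122498
544,0.0118315
546,0.0110863
548,0.010178
550,0.0092463
552,0.00839456
554,0.00769222
556,0.00718502
558,0.00690913
560,0.00690776
562,0.00722437
564,0.00783034
566,0.0086812
568,0.00971626
570,0.0108353
572,0.0118824
574,0.0126471
576,0.0128945
578,0.0124605
580,0.0114063
582,0.00991034
584,0.00818867
586,0.00644724
588,0.0048562
590,0.0035417
592,0.00253645
594,0.00180902
596,0.00130307
598,0.000961407
600,0.000736827
602,0.000592579
604,0.000497326
606,0.000431459
608,0.000383294
610,0.000345388
612,0.000313153
614,0.000284956
616,0.000259939
618,0.000237429
620,0.000216904
622,0.000198043
624,0.000180917
626,0.000165607
628,0.00015213
630,0.000140458
632,0.000130493
634,0.000121986
636,0.000114693
638,0.000108419
640,0.000103001
642,9.83045e-05
644,9.42177e-05
646,9.06457e-05
648,8.7508e-05
650,8.47351e-05
652,8.22702e-05
654,8.00775e-05
656,7.81288e-05
658,7.63991e-05
660,7.48663e-05
662,7.35106e-05
664,7.23139e-05
666,7.12602e-05
668,7.03347e-05
670,6.95238e-05
672,6.88149e-05
674,6.81963e-05
676,6.7657e-05
678,6.71866e-05
680,6.6775e-05
682,6.64155e-05
684,6.61135e-05
686,6.5877e-05
688,6.57142e-05
690,6.56334e-05
692,6.56432e-05
694,6.57525e-05
696,6.59708e-05
698,6.6308e-05
700,6.6775e-05
702,6.7381e-05
704,6.81256e-05
706,6.90067e-05
708,7.00223e-05
710,7.1171e-05
712,7.24517e-05
714,7.38637e-05
716,7.54062e-05
718,7.70787e-05
720,7.88805e-05
722,8.08111e-05
724,8.28696e-05
726,8.50551e-05
728,8.7366e-05
730,8.98008e-05
732,9.23565e-05
734,9.50269e-05
736,9.78041e-05
738,0.000100679
740,0.000103641
742,0.000106678
744,0.000109776
746,0.00011292
748,0.000116092
750,0.000119274
752,0.000122446
754,0.000125603
756,0.000128739
758,0.00013185
760,0.000134931
762,0.00013798
764,0.000140992
766,0.000143965
768,0.000146896
770,0.000149783
772,0.000152624
774,0.000155416
776,0.000158157
778,0.000160847
780,0.000163484
782,0.000166066
784,0.0001686
786,0.00017109
788,0.000173543
790,0.000175965
792,0.000178364
794,0.000180747
796,0.000183123
798,0.000185502
800,0.000187891
802,0.000190299
804,0.000192725
806,0.000195167
808,0.00019762
810,0.000200082
812,0.000202549
814,0.000205018
816,0.000207484
818,0.000209944
820,0.000212394
822,0.000214829
824,0.000217246
826,0.000219639
828,0.000222004
830,0.000224336
832,0.00022663
834,0.000228881
836,0.000231084
838,0.000233234
840,0.000235324
842,0.000237352
844,0.000239316
846,0.000241218
848,0.000243059
850,0.00024484
852,0.000246563
854,0.00024823
856,0.000249842
858,0.000251402
860,0.000252911
862,0.000254371
864,0.000255785
866,0.000257155
868,0.000258483
870,0.000259771
872,0.000261023
874,0.000262241
876,0.000263428
878,0.000264586
880,0.000265718
882,0.000266827
884,0.000267914
886,0.000268979
888,0.000270022
890,0.000271044
892,0.000272044
894,0.000273025
896,0.000273986
898,0.000274927
900,0.00027585
902,0.000276753
904,0.000277632
906,0.000278483
908,0.000279299
910,0.000280075
912,0.000280806
914,0.000281486
916,0.00028211
918,0.000282672
920,0.000283167
922,0.000283589
924,0.000283933
926,0.000284192
928,0.000284363
930,0.000284438
932,0.000284414
934,0.000284285
936,0.000284046
938,0.000283692
940,0.000283218
942,0.000282622
944,0.000281909
946,0.000281088
948,0.000280165
950,0.000279149
952,0.000278048
954,0.00027687
956,0.000275621
958,0.000274311
960,0.000272946
962,0.000271534
964,0.000270082
966,0.000268598
968,0.000267089
970,0.000265562
972,0.000264024
974,0.000262481
976,0.00026094
978,0.000259407
980,0.00025789
982,0.000256391
984,0.000254912
986,0.000253451
988,0.000252007
990,0.000250577
992,0.000249162
994,0.000247759
996,0.000246367
998,0.000244986
1000,0.000243614
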