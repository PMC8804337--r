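# deoxyhemoglobin (Hb) specific absorption per uM tetramer
# synthetic reconstruction: smooth spline through canonical spectral landmarks,
# not a digitized literature table; internally consistent across this package
# unit_tag: specific-absorption mm^-1.uM^-1
wavelength_nm,value
450,0.0138155
452,0.0124411
454,0.0112124
456,0.0101212
458,0.00915799
460,0.00831296
462,0.00757604
464,0.00693755
466,0.00638843
468,0.00592042
470,0.0055262
472,0.00519865
474,0.0049286
476,0.00470796
478,0.00453028
480,0.00439042
482,0.00428434
484,0.00420885
486,0.00416153
488,0.00414056
490,0.00414465
492,0.00417268
494,0.00422272
496,0.00429278
498,0.00438102
500,0.00448561
502,0.00460466
504,0.00473612
506,0.00487773
508,0.00502693
510,0.00518082
512,0.00533711
514,0.00549747
516,0.00566481
518,0.00584244
520,0.00603401
522,0.00624367
524,0.00647611
526,0.00673671
528,0.00703168
530,0.00736827
532,0.00775249
534,0.00818041
536,0.00864395
538,0.00913265
540,0.00963326
542,0.0101294
544,0.0106018
546,0.0110285
548,0.0113985
550,0.0117139
552,0.0119789
554,0.0121998
556,0.0123827
558,0.0125129
560,0.0125539
562,0.0124688
564,0.0122252
566,0.0117986
568,0.0111764
570,0.0103616
572,0.00939004
574,0.00836136
576,0.00736572
578,0.00646312
580,0.00568742
582,0.00505352
584,0.00456496
586,0.00421975
588,0.00399326
590,0.00384665
592,0.00374939
594,0.00367594
596,0.00360341
598,0.0035108
600,0.0033795
602,0.00319998
604,0.00298627
606,0.00275627
608,0.00252494
610,0.00230378
612,0.00210094
614,0.00192175
616,0.00176919
618,0.00164153
620,0.00153401
622,0.00144275
624,0.00136461
626,0.00129705
628,0.00123796
630,0.0011856
632,0.00113858
634,0.00109611
636,0.00105763
638,0.00102262
640,0.000990635
642,0.000961272
644,0.000934179
646,0.000909034
648,0.000885552
650,0.000863469
652,0.000842568
654,0.000822717
656,0.000803812
658,0.000785759
660,0.000768468
662,0.000751857
664,0.000735851
666,0.000720378
668,0.000705373
670,0.000690776
672,0.000676525
674,0.000662555
676,0.000648803
678,0.000635208
680,0.000621716
682,0.000608278
684,0.000594848
686,0.000581387
688,0.000567859
690,0.000554232
692,0.000540456
694,0.000526396
696,0.00051191
698,0.000496879
700,0.000481203
702,0.000464809
704,0.000447647
706,0.000429691
708,0.000410945
710,0.000391439
712,0.000371362
714,0.000351392
716,0.00033221
718,0.000314357
720,0.000298253
722,0.000284225
724,0.000272533
726,0.000263402
728,0.000257054
730,0.000253745
732,0.000253659
734,0.000256499
736,0.000261909
738,0.000269585
740,0.000279234
742,0.00029055
744,0.000303178
746,0.000316703
748,0.000330622
750,0.000344338
752,0.000357159
754,0.000368308
756,0.000376949
758,0.000382229
760,0.000383516
762,0.000380977
764,0.000375066
766,0.000366308
768,0.000355263
770,0.000342497
772,0.000328552
774,0.000313925
776,0.000299062
778,0.000284344
780,0.000270093
782,0.000256548
784,0.000243813
786,0.00023195
788,0.000221
790,0.000210991
792,0.000201939
794,0.000193855
796,0.000186744
798,0.000180609
800,0.000175457
802,0.000171271
804,0.000167937
806,0.000165332
808,0.000163349
810,0.000161892
812,0.000160872
814,0.000160206
816,0.000159818
818,0.00015963
820,0.000159569
822,0.000159573
824,0.000159627
826,0.000159729
828,0.000159879
830,0.000160073
832,0.000160311
834,0.00016059
836,0.000160908
838,0.000161264
840,0.000161656
842,0.000162082
844,0.000162541
846,0.00016303
848,0.000163549
850,0.000164095
852,0.000164666
854,0.00016526
856,0.000165877
858,0.000166513
860,0.000167168
862,0.000167838
864,0.000168524
866,0.000169223
868,0.000169933
870,0.000170653
872,0.000171381
874,0.000172115
876,0.000172855
878,0.000173598
880,0.000174342
882,0.000175085
884,0.000175826
886,0.000176563
888,0.000177294
890,0.000178017
892,0.00017873
894,0.000179432
896,0.000180119
898,0.00018079
900,0.000181444
902,0.000182077
904,0.000182689
906,0.000183278
908,0.000183843
910,0.000184381
912,0.000184892
914,0.000185375
916,0.000185827
918,0.000186247
920,0.000186633
922,0.000186985
924,0.000187301
926,0.000187579
928,0.000187818
930,0.000188016
932,0.000188173
934,0.000188286
936,0.000188354
938,0.000188376
940,0.000188351
942,0.000188279
944,0.000188162
946,0.000188005
948,0.000187811
950,0.000187585
952,0.000187331
954,0.000187052
956,0.000186754
958,0.00018644
960,0.000186113
962,0.000185779
964,0.000185441
966,0.000185102
968,0.000184768
970,0.000184441
972,0.000184125
974,0.000183825
976,0.000183544
978,0.000183287
980,0.000183056
982,0.000182854
984,0.00018268
986,0.00018253
988,0.000182401
990,0.00018229
992,0.000182195
994,0.000182112
996,0.000182038
998,0.000181969
1000,0.000181904
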