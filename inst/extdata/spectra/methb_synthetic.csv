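# methemoglobin (MetHb) specific absorption per uM tetramer
# synthetic reconstruction: smooth spline through canonical spectral landmarks,
# not a digitized literature table; internally consistent across this package
# unit_tag: specific-absorption mm^-1.uM^-1
wavelength_nm,value
450,0.00575646
452,0.00528166
454,0.00484974
456,0.00446
458,0.00411105
460,0.00380107
462,0.00352801
464,0.0032897
466,0.00308404
468,0.00290908
470,0.0027631
472,0.00264406
474,0.00254795
476,0.00247093
478,0.00240981
480,0.00236192
482,0.00232493
484,0.00229681
486,0.0022757
488,0.00225987
490,0.00224769
492,0.00223758
494,0.002228
496,0.00221743
498,0.0022044
500,0.00218746
502,0.00216564
504,0.00213969
506,0.00211076
508,0.00207996
510,0.00204835
512,0.00201693
514,0.00198663
516,0.00195835
518,0.00193292
520,0.00191115
522,0.00189336
524,0.00187821
526,0.00186395
528,0.0018489
530,0.00183144
532,0.00181002
534,0.00178318
536,0.00174958
538,0.00170811
540,0.00165786
542,0.00159886
544,0.0015338
546,0.00146572
548,0.00139731
550,0.00133084
552,0.00126818
554,0.00121087
556,0.00116012
558,0.00111694
560,0.00108221
562,0.00105625
564,0.0010374
566,0.00102372
568,0.00101346
570,0.00100497
572,0.000996692
574,0.0009871
576,0.000974737
578,0.000958292
580,0.000937757
582,0.000914331
584,0.000889199
586,0.000863454
588,0.00083808
590,0.000813954
592,0.000791854
594,0.000772471
596,0.000756438
598,0.000744355
600,0.000736827
602,0.000734271
604,0.000736277
606,0.000742293
608,0.000751819
610,0.000764379
612,0.000779501
614,0.000796694
616,0.000815426
618,0.000834963
620,0.000854344
622,0.000872508
624,0.000888314
626,0.000900562
628,0.000908028
630,0.000909521
632,0.000904242
634,0.000892713
636,0.000875854
638,0.000854638
640,0.000830045
642,0.000803021
644,0.000774457
646,0.000745145
648,0.000715443
650,0.000685341
652,0.000654837
654,0.000623955
656,0.000592738
658,0.000561255
660,0.000529595
662,0.000497949
664,0.000466831
666,0.000436734
668,0.000408046
670,0.000381053
672,0.000355957
674,0.000332884
676,0.000311907
678,0.000293051
680,0.00027631
682,0.000261611
684,0.00024869
686,0.00023728
688,0.000227155
690,0.000218121
692,0.000210013
694,0.000202686
696,0.000196015
698,0.000189888
700,0.000184207
702,0.000178894
704,0.000173913
706,0.000169243
708,0.000164861
710,0.000160749
712,0.000156888
714,0.000153262
716,0.000149855
718,0.000146655
720,0.000143647
722,0.000140819
724,0.000138161
726,0.000135662
728,0.000133312
730,0.000131103
732,0.000129025
734,0.000127072
736,0.000125235
738,0.000123509
740,0.000121886
742,0.000120361
744,0.000118928
746,0.000117582
748,0.000116317
750,0.000115129
752,0.000114014
754,0.000112969
756,0.000111991
758,0.000111077
760,0.000110226
762,0.000109434
764,0.000108701
766,0.000108023
768,0.0001074
770,0.000106829
772,0.000106309
774,0.000105839
776,0.000105415
778,0.000105039
780,0.000104707
782,0.000104419
784,0.000104173
786,0.000103969
788,0.000103806
790,0.000103681
792,0.000103595
794,0.000103546
796,0.000103534
798,0.000103558
800,0.000103616
802,0.000103709
804,0.000103835
806,0.000103994
808,0.000104186
810,0.00010441
812,0.000104666
814,0.000104953
816,0.000105271
818,0.00010562
820,0.000105999
822,0.000106408
824,0.000106846
826,0.000107314
828,0.000107811
830,0.000108337
832,0.000108892
834,0.000109474
836,0.000110085
838,0.000110724
840,0.00011139
842,0.000112084
844,0.000112805
846,0.000113553
848,0.000114328
850,0.000115129
852,0.000115957
854,0.000116809
856,0.000117684
858,0.000118579
860,0.000119494
862,0.000120425
864,0.000121372
866,0.000122331
868,0.000123301
870,0.000124279
872,0.000125262
874,0.00012625
876,0.000127238
878,0.000128225
880,0.000129207
882,0.000130182
884,0.000131147
886,0.0001321
888,0.000133037
890,0.000133955
892,0.000134852
894,0.000135723
896,0.000136566
898,0.000137378
900,0.000138155
902,0.000138895
904,0.000139598
906,0.000140266
908,0.0001409
910,0.000141502
912,0.000142074
914,0.000142617
916,0.000143133
918,0.000143624
920,0.000144091
922,0.000144538
924,0.000144964
926,0.000145374
928,0.000145767
930,0.000146148
932,0.000146516
934,0.000146876
936,0.000147228
938,0.000147575
940,0.000147918
942,0.000148261
944,0.000148606
946,0.000148953
948,0.000149307
950,0.000149668
952,0.000150039
954,0.00015042
956,0.000150811
958,0.000151211
960,0.00015162
962,0.000152037
964,0.000152463
966,0.000152897
968,0.000153339
970,0.000153788
972,0.000154244
974,0.000154707
976,0.000155176
978,0.000155652
980,0.000156133
982,0.000156619
984,0.000157111
986,0.000157607
988,0.000158108
990,0.000158612
992,0.00015912
994,0.000159632
996,0.000160146
998,0.000160662
1000,0.000161181
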