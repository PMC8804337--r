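# pure water absorption per unit volume fraction
# synthetic reconstruction: smooth spline through canonical spectral landmarks,
# not a digitized literature table; internally consistent across this package
# unit_tag: specific-absorption mm^-1 per unit volume-fraction
wavelength_nm,value
450,9.2e-06
452,9.47987e-06
454,9.76837e-06
456,1.00658e-05
458,1.03727e-05
460,1.06894e-05
462,1.10163e-05
464,1.13539e-05
466,1.17028e-05
468,1.20634e-05
470,1.24362e-05
472,1.2822e-05
474,1.32212e-05
476,1.36346e-05
478,1.40628e-05
480,1.45066e-05
482,1.49668e-05
484,1.54442e-05
486,1.59396e-05
488,1.64541e-05
490,1.69886e-05
492,1.75441e-05
494,1.81217e-05
496,1.87228e-05
498,1.93484e-05
500,2e-05
502,2.06791e-05
504,2.13878e-05
506,2.21286e-05
508,2.29041e-05
510,2.37173e-05
512,2.45713e-05
514,2.54696e-05
516,2.64159e-05
518,2.74143e-05
520,2.84694e-05
522,2.9586e-05
524,3.07696e-05
526,3.20261e-05
528,3.33621e-05
530,3.47846e-05
532,3.63016e-05
534,3.79218e-05
536,3.96548e-05
538,4.15112e-05
540,4.35028e-05
542,4.56426e-05
544,4.79451e-05
546,5.04266e-05
548,5.31049e-05
550,5.6e-05
552,5.91324e-05
554,6.25165e-05
556,6.61646e-05
558,7.00895e-05
560,7.43031e-05
562,7.88171e-05
564,8.36423e-05
566,8.87882e-05
568,9.42628e-05
570,0.000100072
572,0.000106221
574,0.000112708
576,0.000119533
578,0.000126689
580,0.000134164
582,0.000141944
584,0.000150007
586,0.000158325
588,0.000166866
590,0.000175589
592,0.000184446
594,0.000193381
596,0.000202333
598,0.000211232
600,0.00022
602,0.000228564
604,0.000236884
606,0.000244933
608,0.000252686
610,0.000260123
612,0.000267226
614,0.00027398
616,0.000280377
618,0.000286409
620,0.000292074
622,0.000297372
624,0.000302307
626,0.000306886
628,0.000311119
630,0.000315018
632,0.000318599
634,0.00032188
636,0.000324879
638,0.000327619
640,0.000330122
642,0.000332414
644,0.00033452
646,0.000336468
648,0.000338285
650,0.00034
652,0.00034165
654,0.0003433
656,0.000345022
658,0.000346891
660,0.000348984
662,0.000351378
664,0.000354155
666,0.000357398
668,0.000361198
670,0.000365648
672,0.00037085
674,0.000376914
676,0.000383961
678,0.000392126
680,0.000401559
682,0.000412429
684,0.000424931
686,0.000439287
688,0.000455755
690,0.000474635
692,0.000496277
694,0.000521096
696,0.000549582
698,0.000582317
700,0.00062
702,0.000663361
704,0.000712813
706,0.000768667
708,0.000831205
710,0.00090065
712,0.000977128
714,0.00106063
716,0.00115098
718,0.00124775
720,0.00135026
722,0.00145749
724,0.00156806
726,0.0016802
728,0.00179171
730,0.0019
732,0.00200252
734,0.00209818
736,0.00218647
738,0.00226711
740,0.00234002
742,0.00240535
744,0.00246343
746,0.00251477
748,0.00256003
750,0.0026
752,0.00263514
754,0.0026643
756,0.00268588
758,0.00269829
760,0.0027
762,0.00269006
764,0.00266941
766,0.00263957
768,0.00260208
770,0.00255851
772,0.00251037
774,0.00245912
776,0.00240614
778,0.00235271
780,0.0023
782,0.00224908
784,0.00220084
786,0.00215611
788,0.00211563
790,0.00208009
792,0.00205017
794,0.00202651
796,0.00200978
798,0.00200069
800,0.002
802,0.00200833
804,0.00202548
806,0.0020511
808,0.00208492
810,0.00212674
812,0.00217641
814,0.00223383
816,0.00229888
818,0.0023715
820,0.00245158
822,0.00253902
824,0.00263366
826,0.00273532
828,0.00284373
830,0.00295856
832,0.00307937
834,0.00320563
836,0.00333666
838,0.00347167
840,0.00360969
842,0.0037496
844,0.00389013
846,0.00402981
848,0.00416703
850,0.0043
852,0.00442712
854,0.00454804
856,0.00466286
858,0.00477174
860,0.00487496
862,0.00497287
864,0.00506592
866,0.00515464
868,0.0052396
870,0.00532147
872,0.00540096
874,0.00547884
876,0.00555596
878,0.00563317
880,0.00571143
882,0.0057917
884,0.00587503
886,0.00596251
888,0.00605532
890,0.00615468
892,0.00626192
894,0.00637847
896,0.00650586
898,0.00664575
900,0.0068
902,0.00697128
904,0.0071653
906,0.00738917
908,0.00765098
910,0.00796012
912,0.00832769
914,0.00876703
916,0.00929446
918,0.00993027
920,0.0107
922,0.0116309
924,0.0127341
926,0.0140141
928,0.0154712
930,0.0170987
932,0.01888
934,0.0207854
936,0.0227693
938,0.0247682
940,0.0267
942,0.0284854
944,0.0301208
946,0.0316363
948,0.0330768
950,0.0345
952,0.0359608
954,0.0374594
956,0.0389788
958,0.0404997
960,0.042
962,0.0434463
964,0.0447667
966,0.0458736
968,0.046675
970,0.047079
972,0.047
974,0.0464046
976,0.0454267
978,0.0442381
980,0.043
982,0.0418343
984,0.0407581
986,0.0397645
988,0.0388471
990,0.038
992,0.0372167
994,0.0364861
996,0.0357967
998,0.035138
1000,0.0345
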