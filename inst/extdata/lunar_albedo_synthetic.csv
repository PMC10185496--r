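"wavelength_nm","value"
400,0.09
401,0.0902
402,0.0904
403,0.0906
404,0.0908
405,0.091
406,0.0912
407,0.0914
408,0.0916
409,0.0918
410,0.092
411,0.0922
412,0.0924
413,0.0926
414,0.0928
415,0.093
416,0.0932
417,0.0934
418,0.0936
419,0.0938
420,0.094
421,0.0942
422,0.0944
423,0.0946
424,0.0948
425,0.095
426,0.0952
427,0.0954
428,0.0956
429,0.0958
430,0.096
431,0.0962
432,0.0964
433,0.0966
434,0.0968
435,0.097
436,0.0972
437,0.0974
438,0.0976
439,0.0978
440,0.098
441,0.0982
442,0.0984
443,0.0986
444,0.0988
445,0.099
446,0.0992
447,0.0994
448,0.0996
449,0.0998
450,0.1
451,0.1002
452,0.1004
453,0.1006
454,0.1008
455,0.101
456,0.1012
457,0.1014
458,0.1016
459,0.1018
460,0.102
461,0.1022
462,0.1024
463,0.1026
464,0.1028
465,0.103
466,0.1032
467,0.1034
468,0.1036
469,0.1038
470,0.104
471,0.1042
472,0.1044
473,0.1046
474,0.1048
475,0.105
476,0.1052
477,0.1054
478,0.1056
479,0.1058
480,0.106
481,0.1062
482,0.1064
483,0.1066
484,0.1068
485,0.107
486,0.1072
487,0.1074
488,0.1076
489,0.1078
490,0.108
491,0.1082
492,0.1084
493,0.1086
494,0.1088
495,0.109
496,0.1092
497,0.1094
498,0.1096
499,0.1098
500,0.11
501,0.1102
502,0.1104
503,0.1106
504,0.1108
505,0.111
506,0.1112
507,0.1114
508,0.1116
509,0.1118
510,0.112
511,0.1122
512,0.1124
513,0.1126
514,0.1128
515,0.113
516,0.1132
517,0.1134
518,0.1136
519,0.1138
520,0.114
521,0.1142
522,0.1144
523,0.1146
524,0.1148
525,0.115
526,0.1152
527,0.1154
528,0.1156
529,0.1158
530,0.116
531,0.1162
532,0.1164
533,0.1166
534,0.1168
535,0.117
536,0.1172
537,0.1174
538,0.1176
539,0.1178
540,0.118
541,0.1182
542,0.1184
543,0.1186
544,0.1188
545,0.119
546,0.1192
547,0.1194
548,0.1196
549,0.1198
550,0.12
551,0.1202
552,0.1204
553,0.1206
554,0.1208
555,0.121
556,0.1212
557,0.1214
558,0.1216
559,0.1218
560,0.122
561,0.1222
562,0.1224
563,0.1226
564,0.1228
565,0.123
566,0.1232
567,0.1234
568,0.1236
569,0.1238
570,0.124
571,0.1242
572,0.1244
573,0.1246
574,0.1248
575,0.125
576,0.1252
577,0.1254
578,0.1256
579,0.1258
580,0.126
581,0.1262
582,0.1264
583,0.1266
584,0.1268
585,0.127
586,0.1272
587,0.1274
588,0.1276
589,0.1278
590,0.128
591,0.1282
592,0.1284
593,0.1286
594,0.1288
595,0.129
596,0.1292
597,0.1294
598,0.1296
599,0.1298
600,0.13
601,0.1302
602,0.1304
603,0.1306
604,0.1308
605,0.131
606,0.1312
607,0.1314
608,0.1316
609,0.1318
610,0.132
611,0.1322
612,0.1324
613,0.1326
614,0.1328
615,0.133
616,0.1332
617,0.1334
618,0.1336
619,0.1338
620,0.134
621,0.1342
622,0.1344
623,0.1346
624,0.1348
625,0.135
626,0.1352
627,0.1354
628,0.1356
629,0.1358
630,0.136
631,0.1362
632,0.1364
633,0.1366
634,0.1368
635,0.137
636,0.1372
637,0.1374
638,0.1376
639,0.1378
640,0.138
641,0.1382
642,0.1384
643,0.1386
644,0.1388
645,0.139
646,0.1392
647,0.1394
648,0.1396
649,0.1398
650,0.14
651,0.1402
652,0.1404
653,0.1406
654,0.1408
655,0.141
656,0.1412
657,0.1414
658,0.1416
659,0.1418
660,0.142
661,0.1422
662,0.1424
663,0.1426
664,0.1428
665,0.143
666,0.1432
667,0.1434
668,0.1436
669,0.1438
670,0.144
671,0.1442
672,0.1444
673,0.1446
674,0.1448
675,0.145
676,0.1452
677,0.1454
678,0.1456
679,0.1458
680,0.146
681,0.1462
682,0.1464
683,0.1466
684,0.1468
685,0.147
686,0.1472
687,0.1474
688,0.1476
689,0.1478
690,0.148
691,0.1482
692,0.1484
693,0.1486
694,0.1488
695,0.149
696,0.1492
697,0.1494
698,0.1496
699,0.1498
700,0.15
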