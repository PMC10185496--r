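"wavelength_nm","value"
400,1.568434
401,1.573258
402,1.578024
403,1.582733
404,1.587385
405,1.59198
406,1.596517
407,1.600997
408,1.60542
409,1.609786
410,1.614096
411,1.618348
412,1.622544
413,1.626684
414,1.630767
415,1.634794
416,1.638765
417,1.64268
418,1.646539
419,1.650342
420,1.65409
421,1.657783
422,1.66142
423,1.665003
424,1.66853
425,1.672003
426,1.675421
427,1.678785
428,1.682095
429,1.685351
430,1.688554
431,1.691702
432,1.694798
433,1.69784
434,1.70083
435,1.703767
436,1.706651
437,1.709483
438,1.712263
439,1.714991
440,1.717668
441,1.720294
442,1.722868
443,1.725391
444,1.727864
445,1.730287
446,1.732659
447,1.734982
448,1.737255
449,1.739478
450,1.741653
451,1.743778
452,1.745855
453,1.747884
454,1.749865
455,1.751797
456,1.753683
457,1.75552
458,1.757311
459,1.759056
460,1.760753
461,1.762405
462,1.76401
463,1.76557
464,1.767085
465,1.768554
466,1.769979
467,1.771359
468,1.772695
469,1.773987
470,1.775235
471,1.77644
472,1.777602
473,1.77872
474,1.779797
475,1.780831
476,1.781823
477,1.782773
478,1.783682
479,1.784549
480,1.785376
481,1.786162
482,1.786909
483,1.787615
484,1.788281
485,1.788908
486,1.789496
487,1.790044
488,1.790555
489,1.791027
490,1.791461
491,1.791857
492,1.792217
493,1.792538
494,1.792823
495,1.793072
496,1.793284
497,1.793461
498,1.793601
499,1.793706
500,1.793776
501,1.793812
502,1.793812
503,1.793779
504,1.793711
505,1.79361
506,1.793475
507,1.793307
508,1.793106
509,1.792873
510,1.792607
511,1.792309
512,1.791979
513,1.791618
514,1.791226
515,1.790803
516,1.790349
517,1.789865
518,1.78935
519,1.788806
520,1.788232
521,1.787629
522,1.786996
523,1.786335
524,1.785646
525,1.784928
526,1.784182
527,1.783408
528,1.782607
529,1.781779
530,1.780924
531,1.780042
532,1.779133
533,1.778199
534,1.777238
535,1.776252
536,1.77524
537,1.774204
538,1.773142
539,1.772055
540,1.770945
541,1.76981
542,1.768651
543,1.767468
544,1.766262
545,1.765032
546,1.76378
547,1.762505
548,1.761208
549,1.759888
550,1.758546
551,1.757182
552,1.755797
553,1.754391
554,1.752963
555,1.751515
556,1.750046
557,1.748556
558,1.747046
559,1.745517
560,1.743967
561,1.742398
562,1.74081
563,1.739203
564,1.737576
565,1.735932
566,1.734268
567,1.732587
568,1.730887
569,1.72917
570,1.727435
571,1.725683
572,1.723913
573,1.722127
574,1.720323
575,1.718504
576,1.716667
577,1.714815
578,1.712947
579,1.711063
580,1.709163
581,1.707248
582,1.705318
583,1.703372
584,1.701412
585,1.699438
586,1.697448
587,1.695445
588,1.693428
589,1.691396
590,1.689351
591,1.687293
592,1.685221
593,1.683136
594,1.681038
595,1.678927
596,1.676804
597,1.674668
598,1.67252
599,1.67036
600,1.668188
601,1.666004
602,1.663808
603,1.661602
604,1.659383
605,1.657154
606,1.654914
607,1.652663
608,1.650401
609,1.648129
610,1.645847
611,1.643554
612,1.641251
613,1.638939
614,1.636617
615,1.634285
616,1.631944
617,1.629594
618,1.627235
619,1.624866
620,1.622489
621,1.620104
622,1.617709
623,1.615307
624,1.612896
625,1.610477
626,1.60805
627,1.605615
628,1.603173
629,1.600723
630,1.598266
631,1.595801
632,1.593329
633,1.590851
634,1.588365
635,1.585872
636,1.583373
637,1.580868
638,1.578356
639,1.575838
640,1.573313
641,1.570783
642,1.568247
643,1.565705
644,1.563157
645,1.560604
646,1.558046
647,1.555482
648,1.552913
649,1.550338
650,1.547759
651,1.545175
652,1.542587
653,1.539993
654,1.537396
655,1.534793
656,1.532187
657,1.529576
658,1.526961
659,1.524342
660,1.52172
661,1.519093
662,1.516463
663,1.513829
664,1.511192
665,1.508551
666,1.505907
667,1.50326
668,1.50061
669,1.497956
670,1.4953
671,1.492641
672,1.489979
673,1.487315
674,1.484648
675,1.481978
676,1.479307
677,1.476633
678,1.473956
679,1.471278
680,1.468597
681,1.465915
682,1.463231
683,1.460545
684,1.457857
685,1.455168
686,1.452477
687,1.449785
688,1.447091
689,1.444396
690,1.4417
691,1.439002
692,1.436304
693,1.433604
694,1.430904
695,1.428203
696,1.425501
697,1.422798
698,1.420094
699,1.417391
700,1.414686
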