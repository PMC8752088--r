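# Molar extinction coefficients of oxy- (eps_hbo) and deoxy-haemoglobin
# (eps_hbr), natural-log base, units 1/(M*cm), tetramer convention.
# SYNTHETIC RECONSTRUCTION of the standard published in-vitro compilation:
# spline interpolation of ~20 anchor wavelengths recalled to ~10% accuracy;
# generated by data-raw/make_extinction.R. Suitable for self-consistent
# forward/inverse spectroscopy; replace with a measured table for absolute
# quantification of real recordings.
wavelength_nm	eps_hbo	eps_hbr
450	144639.2	218745.6
451	139515.7	209524.9
452	134607.1	200558.6
453	129907.9	191848.2
454	125412.7	183395.1
455	121116	175200.5
456	117012.4	167265.9
457	113096.3	159592.7
458	109362.4	152182.3
459	105805.1	145035.9
460	102419	138155.1
461	99198.3	131542.1
462	96136	125203.1
463	93224.9	119145
464	90457.6	113374.9
465	87826.8	107899.8
466	85325.4	102726.7
467	82945.9	97862.8
468	80681.1	93314.9
469	78523.8	89090.2
470	76466.5	85195.6
471	74503.7	81633.6
472	72635.4	78387.5
473	70863.7	75436.3
474	69190.2	72758.5
475	67616.9	70333.2
476	66145.4	68138.9
477	64777.8	66154.5
478	63515.7	64358.9
479	62361	62730.7
480	61315.5	61248.8
481	60378.4	59893.9
482	59537.7	58654.8
483	58778.8	57522.4
484	58087.3	56487.5
485	57448.4	55540.7
486	56847.7	54673
487	56270.5	53875.1
488	55702.3	53137.8
489	55128.5	52451.9
490	54534.4	51808.2
491	53909.5	51199.8
492	53258.8	50629.5
493	52591.2	50102.2
494	51915.7	49622.9
495	51241.2	49196.6
496	50576.7	48828.5
497	49931.1	48523.3
498	49313.5	48286.3
499	48732.7	48122.4
500	48197.7	48036.5
501	47716.2	48031.9
502	47290.7	48103.9
503	46922.4	48246
504	46612.7	48451.6
505	46362.6	48714.4
506	46173.5	49027.8
507	46046.7	49385.2
508	45983.2	49780.2
509	45984.5	50206.3
510	46051.7	50656.9
511	46190.7	51128
512	46426	51625.6
513	46786.5	52158
514	47301.5	52733.7
515	48000	53360.9
516	48911	54048.1
517	50063.6	54803.7
518	51486.9	55636.1
519	53210.1	56553.6
520	55262	57564.6
521	57661.5	58676.6
522	60385.2	59893.1
523	63399.3	61216.4
524	66670.3	62649.1
525	70164.4	64193.8
526	73847.8	65852.8
527	77686.9	67628.7
528	81647.9	69524
529	85697.1	71541.2
530	89800.8	73682.7
531	93920.5	75946.1
532	97997.9	78308.7
533	101970	80742.8
534	105773.8	83221
535	109346.2	85715.5
536	112624.3	88198.7
537	115544.9	90643
538	118045.1	93020.7
539	120061.8	95304.3
540	121531.9	97466.1
541	122392.5	99478.4
542	122580.4	101313.7
543	122053.4	102960.4
544	120852	104471
545	119037.1	105914.1
546	116670.1	107358.2
547	113812	108872
548	110524.1	110524.1
549	106877.4	112357.5
550	102983.2	114313.6
551	98962.8	116308
552	94937.5	118256.7
553	91028.5	120075.3
554	87357	121679.7
555	84044.4	122985.7
556	81195.7	123923
557	78851.7	124478
558	77037.1	124650.9
559	75776.4	124442
560	75094.2	123851.4
561	75028.5	122879.2
562	75670.8	121523.3
563	77125.8	119781.3
564	79498.3	117650.7
565	82893.1	115129.3
566	87334.1	112254
567	92521.9	109220.2
568	98076.1	106262.7
569	103616.3	103616.3
570	108824.8	101451.3
571	113634.3	99679.9
572	118039.9	98149.8
573	122037	96708.6
574	125544.2	95237.9
575	128174	93754.4
576	129462.2	92309
577	128944.8	90952.1
578	126276.5	89676.3
579	121588.2	88240.8
580	115129.3	86346.9
581	107182	83781.3
582	98158.5	80672.6
583	88503.4	77234.8
584	78661.6	73682.2
585	69077.6	70228.8
586	60129.2	67035.4
587	51927.2	64048.7
588	44515.2	61162
589	37936.9	58268.7
590	32236.2	55262
591	27429.1	52079.3
592	23420.9	48834
593	20089.3	45683.3
594	17312.1	42784.6
595	14966.8	40295.2
596	12946.6	38327
597	11206.4	36809.2
598	9716.4	35625.4
599	8446.9	34659.5
600	7368.3	33795
601	6453.2	32935.9
602	5684.3	32066.8
603	5046.6	31192.4
604	4524.9	30317.7
605	4104.4	29447.2
606	3770	28586
607	3506.6	27738.6
608	3299.5	26910.1
609	3133.4	26105.1
610	2993.4	25328.4
611	2866.8	24583.2
612	2750.4	23865.3
613	2643.2	23169.2
614	2544.3	22488.9
615	2452.8	21818.9
616	2367.6	21153.3
617	2287.9	20486.4
618	2212.8	19812.5
619	2141.2	19125.8
620	2072.3	18420.7
621	2005.3	17694.1
622	1940.1	16954.1
623	1876.9	16211.6
624	1815.6	15477.4
625	1756.5	14762.5
626	1699.7	14077.6
627	1645.1	13433.6
628	1593.1	12841.5
629	1543.5	12312
630	1496.7	11856
631	1452.5	11481
632	1411	11181.1
633	1371.8	10946.9
634	1334.9	10769
635	1300.1	10638.1
636	1267.2	10544.9
637	1236	10479.9
638	1206.5	10434
639	1178.3	10397.7
640	1151.3	10361.6
641	1125.4	10317.2
642	1100.4	10258.4
643	1076.3	10180
644	1052.9	10076.5
645	1030.1	9942.9
646	1007.8	9773.6
647	985.8	9563.4
648	964.1	9307.1
649	942.6	8999.3
650	921	8634.7
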