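tasirna_id	tasirna_sequence	target_id	target_annotation	miru_start	miru_end	cut_site
LOC_Os02g18750.1(189)21 3'D26(+)	UGUGCCACGUCAACACCACCA	LOC_Os03g40260.1	Regulator of chromosome condensation domain containing protein	1676	1696	1687
LOC_Os02g18750.1(192)21 3'D25(+)	GCGCCACUGCCGUCGACGUGU	LOC_Os02g39380.1	OsCML17 - Calmodulin-related calcium sensor protein	343	363	354
LOC_Os02g18750.1(204)21 3'D13(+)	UCGACUUCGCCGCCUCGGCGC	LOC_Os02g39090.1	expressed protein	802	823	814
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os01g15520.1	expressed protein	1248	1268	1259
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os01g34620.8	OsGrx_S15.1 - glutaredoxin subgroup II	500	520	511
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os03g50070.1	DUF1295 domain containing protein	1195	1215	1206
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os04g38450.1	gamma-glutamyltranspeptidase 1 precursor	2137	2157	2148
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os04g49160.1	zinc finger, C3HC4 type domain containing protein	1093	1113	1104
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os05g03574.1	expressed protein	648	668	659
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os06g23274.1	zinc finger, C3HC4 type, domain containing protein	4632	4652	4643
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os06g47850.1	zinc finger family protein	97	117	108
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os08g19114.1	expressed protein	2050	2070	2061
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os08g40440.1	dihydroflavonol-4-reductase	1315	1335	1326
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os09g12230.1	ubiquitin-conjugating enzyme	1021	1041	1032
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os09g27500.1	cytochrome P450	1714	1734	1725
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os11g41860.1	OsFBX429 - F-box domain containing protein	1030	1050	1041
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os11g41860.2	OsFBX429 - F-box domain containing protein	973	993	984
LOC_Os05g43650.1(1540)21 3'D2(+)	UCAAUAUGAAUGUGGAAAAUG	LOC_Os12g12950.1	expressed protein	1071	1091	1082
LOC_Os05g43650.1(1540)21 3'D2(-)	UUUUCCACAUUCAUAUUGAUG	LOC_Os02g45650.1	peptidase	1760	1780	1771
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os02g05810.1	expressed protein	1330	1350	1341
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os02g05810.2	expressed protein	1324	1344	1335
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os02g52900.2	glutaredoxin 2	2034	2054	2045
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os02g53000.2	lysM domain-containing GPI-anchored protein precursor	1340	1360	1351
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os04g44590.1	expressed protein	651	671	662
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os04g44590.5	expressed protein	445	465	456
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os05g41190.1	expressed protein	1026	1046	1037
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os05g41190.2	expressed protein	1082	1102	1093
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os05g51140.1	expressed protein	929	949	940
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os05g51140.2	expressed protein	1586	1606	1597
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os09g33930.1	farnesyltransferase/geranylgeranyltransferase type-1 subunit alpha	1457	1477	1468
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os09g33930.2	farnesyltransferase/geranylgeranyltransferase type-1 subunit alpha	1454	1474	1465
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os09g33930.3	farnesyltransferase/geranylgeranyltransferase type-1 subunit alpha	1740	1760	1751
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os09g33930.4	farnesyltransferase/geranylgeranyltransferase type-1 subunit alpha	1453	1473	1464
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os09g33930.5	farnesyltransferase/geranylgeranyltransferase type-1 subunit alpha	1375	1395	1386
LOC_Os05g43650.1(1542)21 3'D1(+)	AAUGAAUCUAGACAUAUAUAU	LOC_Os12g37510.1	UDP-glucoronosyl and UDP-glucosyltransferase domain containing	1584	1604	1595
LOC_Os05g43650.1(1543)21 3'D2(-)	GCAUUUUCCACAUUCAUAUUG	LOC_Os02g48390.1	phosphoribosyltransferase	1758	1778	1769
LOC_Os05g43650.1(1543)21 3'D3(-)	UUCACAAUGUAAGUCAUUUUA	LOC_Os04g39600.1	fasciclin domain containing protein	1020	1040	1031
LOC_Os05g43650.1(1543)21 3'D3(-)	UUCACAAUGUAAGUCAUUUUA	LOC_Os07g01130.1	pentatricopeptide containing protein	4240	4260	4251
LOC_Os05g43650.1(1543)21 3'D1(+)	AUGAAUCUAGACAUAUAUAUC	LOC_Os12g40920.1	bZIP transcription factor domain containing protein	1312	1332	1323
LOC_Os06g30680.1(62)21 3'D2(+)	CAUGGACAACUUCCUGCACAG	LOC_Os05g46580.1	polyprenylsynthetase	1365	1385	1376
LOC_Os12g42380.1(414)21 5'D7(+)	UUUCUUCCAAGAGAGAGUAAG	LOC_Os07g47700.1	NAD dependent epimerase/dehydratase family domain containing protein	1753	1773	1764
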