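wavenumber_cm1	catabolite	stage	refined_stage	spatially_unique	bond_vibration
881	Pheophorbide-a	early	early	FALSE	w(CH)B-C, w(CH)A-B
1107	py-Pheophorbide-a	early	early	FALSE	w(CH)D
1138	Pheophytin-a	early	early	FALSE	w(CH)A-D, w(CH)D
1160	py-Pheophorbide-a	early	early	FALSE	w(CH)A-D
1321	Pheophytin-a	early	early	FALSE	rho(CH2)Phytol
1346	Pheophytin-a	early	early	FALSE	w(NH)A, w(CH)D
1366	Chlorophyllide-a	early	early	FALSE	rho(CH2)[(D)-CH2-CH2-COOH], w(CH)D
1369	Chlorophyll-a	early	early	FALSE	rho(CH2)[(D)-CH2-CH2-COOPhytol], w(CH)D
1374	Pheophorbide-a	early	early	FALSE	rho(CH2)[(B)-CH2-CH3], rho(CH3)[(B)-CH2-CH3], rho(CH3)[(B)-CH3], rho(CH3)[(C)-CH3]
1378	py-Pheophorbide-a	early	early	FALSE	nus(CH3)[(C)-CH3], w(NH)C, w(CH)D
1396	Chlorophyll-b	early	early	FALSE	rho(CH2)[(D)-CH2-CH2-COOPhytol], w(CH)D, rho(CH3)[(A)-CH3]
1406	Pheophorbide-a	early	early	FALSE	rho(CH3)[(C)-CH3], rho(CH3)[(D)-CH3], rho(CH2)[(A)-CH=CH2]
1430	Chlorophyll-b	early	early	FALSE	nu(CH3)[(A)-CH3]
1435	Chlorophyllide-a	early	early	FALSE	nu(CH3)[(A)-CH3], nu(CH3)[(D)-CH3]
1445	ChlC-YTPP-1	late	late	FALSE	rho(CH2)[(D)-CH2-CH2-COOH], nu(CH3)[(D)-CH3], w(CH)A-D, w(NH)A
1460	NChlC	mid	mid	FALSE	nu(CH3)[(D)-CH3], nus(CH2)[(D)-CH2-CH2-COOH]
1474	MV-MM	late	late	FALSE	nu(CH3)[(Ring)-CH3], nu(NH)Ring
1475	Pheophytin-a	early	early	FALSE	nu(CH3)[(D)-CH3], nu(CH3)[(C)-CH3], w(CH)B-C
1475	py-Pheophorbide-a	early	early	FALSE	nu(CH3)[(A)-CH3], nu(CH3)[(C)-CH3], nus(CH2)[(D)-CH2-CH2-COOH]
1479	DNChlC	mid	mid	FALSE	rho(CH2)A-D, nu(C-C)C-D, rho(CH2)[(D)-CH2-CH2-COOH]
1489	Chlorophyll-b	early	early	FALSE	nu(CH3)[(A)-CH3]
1490	DChlC-YTPP-1	late	late	TRUE	nu(C=C)C-D, w(CH)[-C-CH-COOCH3], nu(CH3)[-C=CH-COOCH3]
1494	py-NChlC	mid	mid	FALSE	nu(C-N-C)D, nus(CH2)[(A)-CH2-(D)], rho(CH2)[(D)-CH2-CH2-COOH]
1495	C-E-RD	late	quasi-mid	TRUE	nu(C=C)C, nu(CH3)[(C)-CH3], w(NH)C, w(CH)[(C)-CHO]
1501	Chlorophyllide-a	early	early	FALSE	nu(C=N)A, nu(CH3)[(A)-CH3], nu(C-C)[(A)-CH-CH2], nus(CH2)[(A)-CH-CH2]
1501	Chlorophyll-b	early	early	FALSE	nu(C=N)A, nu(CH3)[(D)-CH3], nu(C-C)[(A)-CH-CH2], nus(CH2)[(A)-CH-CH2]
1510	bc-NChlC	late	late	TRUE	rho(CH2)[(B)-CH2-CH2-O-Glsy], rho(CH2)[(D)-CH2-CH2-COO-CH2-Glsy]
1510	DChlC-YTPP-2	late	late	TRUE	nu(CH3)[(D)-CH3], nu(C-C)D, rho(CH2)[(D)-CH2-CH2-COOH], nu(C=C)[-C=CH-COOH]
1531	pFChlC	mid	mid	FALSE	nu(CH3)[(C)-CH3], nu(C=C)C, nu(C-C)E
1535	C-E-RD	late	quasi-mid	TRUE	nu(C-C)[(C)-CHO], w(NH)C, nu(C=C)C, nu(CH3)[(C)-CH3]
1540	bc-FChlC	late	late	FALSE	nu(CH3)[(C)-CH3], nu(C=C)C, nu(C-N)C, nu(C-C)E
1541	Pheophorbide-a	early	early	FALSE	nu(C=C)D-E, nu(C=N)C, nu(C-C)B
1566	Chlorophyllide-a	early	early	FALSE	nu(C-C)A, nu(C-C)A-B
1567	Chlorophyll-a	early	early	FALSE	nu(C-C)A, nu(C-C)A-B
1572	Chlorophyll-b	early	early	FALSE	nu(C-C)A, g(C-C)B
1587	Pheophorbide-a	early	early	FALSE	nu(C-N)C, w(NH)C, nu(C=C)B=C, nu(C=C)B, nu(C=N)B
1611	Pheophytin-a	early	early	FALSE	nu(C-N)A, w(NH)A, nu(C-C)A
1616	DPiChlC	mid	mid	FALSE	nu(C-N)D, nu(C=C)A-D
1619	bc-FChlC	late	late	FALSE	nu(C-N)D, w(CH)A-D
1619	Chlorophyllide-a	early	early	FALSE	nu(C=C)B, nu(C=C)[B=C-C], nu(C=C)C
1619	PiChlC	mid	mid	FALSE	nu(C-N)D, nu(C=C)A-D, nu(C-N)C
1623	Chlorophyll-a	early	early	FALSE	nu(C=C)B-C, nu(C-N)B, nu(C=C)C
1629	Chlorophyll-b	early	early	FALSE	nu(C-C)D-E, nu(C=C)C, nu(C=C)D
1631	py-Pheophorbide-a	early	early	FALSE	nu(C=C)A-D, nu(C-C)C, nu(C=C)A-B
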