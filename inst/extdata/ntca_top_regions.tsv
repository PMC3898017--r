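id	nlq	start	end	site_pos	site_seq	promoter_seq
1203	8186.60	3561438	3561710	3561528	GTGTGTCTTGATAC	GTGTGTCTTGATACAATACTTTTAAGATGACTGTTATATGCTTTCTAAG
1856	7861.39	5515960	5516178	5516125	GAATTACTGACTAC	GAATTACTGACTACAGAATTCCCGCATTAACTTAGCTATCATCTGAGGTT
1152	7152.53	3427339	3427611	3427445	GTAACATGAGATAC	GTAACATGAGATACACAATAGCATTTATATTTGCTTTAGTATCTCTCTC
390	6288.90	1156154	1156424	1156258	GTATTAACTAATAC	
798	5358.67	2400656	2400888	2400815	GTATATTTCAACAC	
931	4728.32	2807226	2807511	2807342	GTAACAAAGACTAC	
1612	4089.39	4795414	4795682	4795535	GTAGCTATCACTAC	
293	3663.48	815417	815662	815545	GTATAAATTTTTAC	
364	3580.62	1070920	1071178	1071039	GTAGCCCCTGCTAC	
1764	3570.57	5243203	5243472	5243396	GTATTGAAAATTAC	
1165	3408.52	3463447	3463731	3463590	GTTACACCTGCTAC	
1125	3369.20	3341106	3341375	3341205	GTATAACTTGATGC	
1530	3353.43	4573161	4573410	4573340	GTTAAATAGATTAC	
932	3292.44	2809205	2809466	2809350	GTAGCATAAGATAC	
2098	3220.20	6294152	6294404	6294223	GTTGATTTGGATAC	
319	3192.18	902825	903070	902941	GTAGCCATGAATAC	
1150	3126.82	3420486	3420738	3420576	GCTGAGATTGGTAC	
2232	2974.32	264949	265189	265067	GTAGCCTGTGATAC	
898	2824.47	2729431	2729698	2729550	GTATTGCTGGCTAC	
1858	2807.34	5523157	5523405	5523288	GTATAAGCTGTAAC	
1255	2798.00	3732951	3733219	3733071	GTTAAAATGACGAC	
260	2698.90	701137	701391	701297	GTAACAAAATCTAC	GTAACAAAATCTACCAAATTGGGGAGCAAAATCAGCTAACTTAATTGAA
377	2641.34	1111093	1111337	1111206	GTAGCATAGACAAC	
519	2592.23	1576957	1577227	1577115	GTAACATACACTAC	GTAACATACACTACGAAACTTATGCTATGTTAGGAAGAA
2149	2572.01	23295	23563	23435	GTATTCGCTGATAC	
554	2517.34	1669629	1669873	1669702	GTGACTGGGGATAC	
1784	2362.05	5312632	5312908	5312767	GTATCAACTGCTAC	
1660	2280.02	4946500	4946770	4946621	GTAGCAGGTTATAC	
2345	2253.01	105303	105553	81139	GTATGAAATAGTAC	
38	2141.66	69752	69991	69882	GTATAGCAAAATAC	
1118	2134.47	3325955	3326229	3326057	GTTACTAAAGATAC	
1283	2115.10	3807024	3807271	3807189	GTATCGACCATTAC	
94	2063.99	210284	210541	210417	GTATTACCTAATAC	
1316	1948.08	3903915	3904189	3904009	GTAACCAAATATAC	
262	1927.75	704040	704304	704169	GTAGCTACTTATAC	
729	1908.73	2158958	2159198	2159129	GTATCCTCTGCTGC	
1923	1885.93	5718871	5719130	5718952	GATACGATTGATAC	
2111	1840.96	6328022	6328296	6328115	GTAGTTTTCGCTAC	
695	1791.79	2058723	2059007	2058829	GTAACCTATAAGAC	
776	1744.65	2304064	2304320	2304193	GAAGTGTGCTGTAC	
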