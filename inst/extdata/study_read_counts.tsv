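Virus	length	DMGA	DMGApos	DMGAneg	DMGE	DMGEpos	DMGEneg	DMGD	DMGDpos	DMGDneg	PMA	PMApos	PMAneg	PMGA	PMGApos	PMGAneg
ElaOMV1 RNA1	3192	0	0	0	0	0	0	0	0	0	4810	3360	1450	0	0	0
ElaOMV1 RNA2	1543	0	0	0	0	0	0	0	0	0	2072	1814	258	0	0	0
ElaOMV2 RNA1	2478	0	0	0	0	0	0	0	0	0	3780	518	3262	0	0	0
ElaOMV2 RNA2	1875	0	0	0	0	0	0	0	0	0	2898	462	2436	0	0	0
PvlaOMV1 RNA1	3040	0	0	0	1492	1028	464	678	410	268	0	0	0	5216	3816	1400
PvlaOMV1 RNA2	1555	0	0	0	958	752	206	542	382	160	0	0	0	990	858	132
PvlaOMV3 RNA1	2406	2654	542	2112	244	58	186	3338	768	2570	840	184	656	3788	834	2954
PvlaOMV3 RNA2	1771	3160	702	2458	600	190	410	3002	888	2114	1060	210	850	2844	722	2122
PvlaOMV4 RNA1	2554	594	588	6	0	0	0	0	0	0	0	0	0	0	0	0
PvlaOMV4 RNA2	1757	1022	1020	2	0	0	0	0	0	0	0	0	0	0	0	0
PvlaOMV5 RNA1	2406	0	0	0	0	0	0	432	402	30	0	0	0	0	0	0
PvlaOMV5 RNA2	1788	0	0	0	0	0	0	314	276	38	0	0	0	0	0	0
ElaOMV3 RNA1	2058	0	0	0	14	0	14	0	0	0	0	0	0	4464	834	3630
ElaOMV3 RNA2	1871	0	0	0	64	12	52	18	2	16	0	0	0	2940	588	2352
ElaOMV4 RNA1	2548	0	0	0	0	0	0	0	0	0	0	0	0	1612	1568	44
ElaOMV4 RNA2	1881	0	0	0	0	0	0	0	0	0	0	0	0	4332	4244	88
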