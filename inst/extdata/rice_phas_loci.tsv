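locus_id	annotation	k	region_start	region_end	trigger_id	trigger_sequence	binding_start	binding_end	cleavage_site
LOC_Os01g57968.1	expressed protein	21	361	1765	OSsRNA-1	GCUUUUUUGAACUUUUUCAUU	424	444	435
LOC_Os02g18750.1	expressed protein	21	188	920	OSsRNA-2	UUUUUUGGCAUUCUGUAACUUG	176	197	188
LOC_Os04g25740.1	expressed protein	21	1908	2159	osa-miR2118f	UUCCUGAUGCCUCCCAUUCCUA	1875	1896	1887
LOC_Os05g43650.1	expressed protein	21	1494	1620	OSsRNA-3	GAUUCAUUAACUUCAAUAUGAA	1528	1549	1540
LOC_Os06g30680.1	WD domain, G-beta repeat domain containing protein	21	62	208	OSsRNA-4	UUCCUGGAGCCGCUCAUUCCAU	50	71	62
LOC_Os01g37325.1	retrotransposon protein	24	1565	1760	OSsRNA-14	AAAAGUAGAUGGAUGCGGAGAC	1676	1697	1688
LOC_Os02g20200.1	retrotransposon protein	24	4856	5052	OSsRNA-15	UAGAUGCUGUCCUGAAAAGGUG	4873	4894	4885
LOC_Os02g20200.1	retrotransposon protein	24	4856	5052	OSsRNA-16	AGCCAUGCUAGUCUAAGAGGG	5007	5027	5018
LOC_Os02g55550.1	F-box/LRR-repeat protein 14	24	905	1101	OSsRNA-17	UAGAUGCUGUCCUGAAAAGGUG	922	943	934
LOC_Os04g45834.2	DUF584 domain containing protein	24	1051	1307	OSsRNA-18	UUAAUAUUUAUAAUUAGUGUCU	1103	1124	1115
LOC_Os04g45834.2	DUF584 domain containing protein	24	1051	1307	OSsRNA-19	UUAAUAUUUAUAAUUAAUGUCC	1103	1124	1115
LOC_Os09g14490.1	TIR-NBS type disease resistance protein	24	4585	4757	OSsRNA-20	UAGAUGCUGUCCUGAAAAGGUG	4578	4599	4590
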