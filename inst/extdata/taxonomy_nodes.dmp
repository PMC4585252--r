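1	|	1	|	no rank	|
2	|	1	|	superkingdom	|
2157	|	1	|	superkingdom	|
1224	|	2	|	phylum	|
203682	|	2	|	phylum	|
976	|	2	|	phylum	|
651137	|	2157	|	phylum	|
1236	|	1224	|	class	|
28211	|	1224	|	class	|
2000	|	203682	|	class	|
3000	|	651137	|	class	|
4000	|	976	|	class	|
2010	|	2000	|	order	|
2020	|	2000	|	order	|
3010	|	3000	|	order	|
4010	|	4000	|	order	|
1100	|	1236	|	order	|
1110	|	1236	|	order	|
2050	|	2010	|	genus	|
2060	|	2020	|	genus	|
3050	|	3010	|	genus	|
3060	|	3010	|	genus	|
4050	|	4010	|	genus	|
1150	|	1100	|	genus	|
1160	|	1110	|	genus	|
28212	|	28211	|	order	|
1170	|	28212	|	genus	|
2101	|	2050	|	species	|
2102	|	2050	|	species	|
2103	|	2060	|	species	|
2104	|	2060	|	species	|
3101	|	3050	|	species	|
3102	|	3050	|	species	|
3103	|	3060	|	species	|
3104	|	3060	|	species	|
1151	|	1150	|	species	|
1152	|	1150	|	species	|
1161	|	1160	|	species	|
1171	|	1170	|	species	|
4101	|	4050	|	species	|
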