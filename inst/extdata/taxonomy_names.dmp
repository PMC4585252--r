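1	|	root	|		|	scientific name	|
2	|	Bacteria	|		|	scientific name	|
2157	|	Archaea	|		|	scientific name	|
1224	|	Proteobacteria	|		|	scientific name	|
203682	|	Planctomycetes	|		|	scientific name	|
976	|	Bacteroidetes	|		|	scientific name	|
651137	|	Thaumarchaeota	|		|	scientific name	|
1236	|	Gammaproteobacteria	|		|	scientific name	|
28211	|	Alphaproteobacteria	|		|	scientific name	|
2000	|	Planctomycetia	|		|	scientific name	|
3000	|	Nitrososphaeria	|		|	scientific name	|
4000	|	Flavobacteriia	|		|	scientific name	|
2010	|	Candidatus Brocadiales	|		|	scientific name	|
2020	|	Planctomycetales	|		|	scientific name	|
3010	|	Nitrosopumilales	|		|	scientific name	|
4010	|	Flavobacteriales	|		|	scientific name	|
1100	|	Alteromonadales	|		|	scientific name	|
1110	|	Thiotrichales	|		|	scientific name	|
2050	|	Candidatus Scalindua	|		|	scientific name	|
2060	|	Planctomyces	|		|	scientific name	|
3050	|	Nitrosopumilus	|		|	scientific name	|
3060	|	Nitrosoarchaeum	|		|	scientific name	|
4050	|	Polaribacter	|		|	scientific name	|
1150	|	Alteromonas	|		|	scientific name	|
1160	|	Thiomicrospira	|		|	scientific name	|
28212	|	Rhodobacterales	|		|	scientific name	|
1170	|	Roseobacter	|		|	scientific name	|
2101	|	Candidatus Scalindua profunda-like sp. 1	|		|	scientific name	|
2102	|	Candidatus Scalindua profunda-like sp. 2	|		|	scientific name	|
2103	|	Planctomyces sp. synth-1	|		|	scientific name	|
2104	|	Planctomyces sp. synth-2	|		|	scientific name	|
3101	|	Nitrosopumilus maritimus-like sp. 1	|		|	scientific name	|
3102	|	Nitrosopumilus maritimus-like sp. 2	|		|	scientific name	|
3103	|	Nitrosoarchaeum sp. synth-1	|		|	scientific name	|
3104	|	Nitrosoarchaeum sp. synth-2	|		|	scientific name	|
1151	|	Alteromonas sp. synth-1	|		|	scientific name	|
1152	|	Alteromonas sp. synth-2	|		|	scientific name	|
1161	|	Thiomicrospira sp. synth-1	|		|	scientific name	|
1171	|	Roseobacter sp. synth-1	|		|	scientific name	|
4101	|	Polaribacter sp. synth-1	|		|	scientific name	|
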