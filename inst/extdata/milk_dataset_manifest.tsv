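dataset_id	source_ref	dim	dryoff_day	technique	max_g	acidification	major_protein_depletion	breed	country	fraction_class	stage_class	factor_note
1	CR15	1		sucrose_gradient		FALSE	FALSE	Holstein-Friesian	Australia	exosomes	colostrum	12 and 24 h post-partum
2	CR15	2		sucrose_gradient		FALSE	FALSE	Holstein-Friesian	Australia	exosomes	colostrum	48 h post-partum
3	CR15	3		sucrose_gradient		FALSE	FALSE	Holstein-Friesian	Australia	exosomes	colostrum	72 h post-partum
4	CR39	5		sucrose_gradient		FALSE	FALSE	Holstein	China	exosomes	colostrum	0 to 5 d post-partum
5	CR22	1		cream_separation		FALSE	FALSE	Holstein	USA	MFGM	colostrum	1 d post-partum
6	CR22	7		cream_separation		FALSE	FALSE	Holstein	USA	MFGM	early	7 d post-partum
7	CR10	14		cream_separation		FALSE	FALSE	Holstein-Friesian		MFGM	early	dry period length
8	CR40	14		cream_separation		FALSE	FALSE	Holstein	China	MFGM	early	breed Holstein
9	CR42	2		centrifugation	3000	TRUE	TRUE	Holstein	Brazil	skimmed	colostrum	48 h post-partum
10	CR42	3		centrifugation	3000	TRUE	TRUE	Holstein	Brazil	skimmed	colostrum	72 h post-partum
11	CR41	1		centrifugation	3000	FALSE	FALSE	Holstein-Friesian	Denmark	skimmed	colostrum	1 d post-partum
12	CR17	1		centrifugation	3000	FALSE	FALSE	Holstein-Friesian	Denmark	skimmed	colostrum	1 d post-partum
13	CR17	10		centrifugation	3000	FALSE	FALSE	Holstein-Friesian	Denmark	skimmed	early	10 d post-partum
14	CR13	14		centrifugation	3000	FALSE	FALSE	Holstein-Friesian	Denmark	skimmed	early	milk fractionation
15	CR45	50		centrifugation	3000	FALSE	FALSE	Holstein	USA	skimmed	peak	low RDP:RUP ratio
16	CR45	50		centrifugation	3000	FALSE	FALSE	Holstein	USA	skimmed	peak	high RDP:RUP ratio
17	CR50	100		centrifugation	3000	FALSE	FALSE	Holstein	China	skimmed	mid	corn-grain based diet
18	CR48	100		centrifugation	3000	TRUE	FALSE	Holstein-Friesian	Denmark	skimmed	mid	3 h post-challenge by E. coli
19	CR51	100		centrifugation	3000	FALSE	FALSE	Holstein-Friesian	Australia	skimmed	mid	breed Holstein-Friesian
20	CR51	100		centrifugation	3000	FALSE	FALSE	Jersey	Australia	skimmed	mid	breed Jersey
21	CR49	100		centrifugation	3000	FALSE	FALSE	Holstein-Friesian	Spain	skimmed	mid	healthy
22	CR47	100		centrifugation	3000	FALSE	FALSE	Holstein	USA	skimmed	mid	healthy
23	CR41	1		centrifugation	100000	FALSE	FALSE	Holstein-Friesian	Denmark	whey	colostrum	1 d post-partum
24	CR43	5		centrifugation	100000	FALSE	FALSE	Holstein	China	whey	colostrum	0 to 5 d post-partum
25	CR44	0		ultracentrifugation	150000	FALSE	FALSE	Holstein-Friesian	Belgium	whey	colostrum	calving day
26	CR52		3	centrifugation	100000	FALSE	FALSE	Holstein-Friesian	New Zealand	whey	drying_off	3 d post drying-off
27	CR52		8	centrifugation	100000	FALSE	FALSE	Holstein-Friesian	New Zealand	whey	drying_off	8 d post drying-off
28	CR13	14		centrifugation	100000	FALSE	FALSE	Holstein-Friesian	Denmark	whey	early	milk fractionation
29	CR44	9		ultracentrifugation	150000	FALSE	FALSE	Holstein-Friesian	Belgium	whey	early	9 d post-partum
30	CR46	50		ultracentrifugation	150000	TRUE	TRUE	Holstein	USA	whey	peak	breed Holstein
31	CR46	50		ultracentrifugation	150000	TRUE	TRUE	Holstein	USA	whey	peak	breed Jersey
32	CR45	50		ultracentrifugation	150000	TRUE	TRUE	Holstein	USA	whey	peak	low RDP:RUP ratio
33	CR45	50		ultracentrifugation	150000	TRUE	TRUE	Holstein	USA	whey	peak	high RDP:RUP ratio
34	CR52	100		centrifugation	100000	FALSE	FALSE	Holstein-Friesian	New Zealand	whey	mid	full lactation
35	CR53	100		centrifugation	100000	FALSE	FALSE		United Kingdom	whey	mid	0 h post-challenge by S. uberis
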