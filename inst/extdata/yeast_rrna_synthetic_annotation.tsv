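contig	position	canonical	mod_code	guide
18S	73	G	Gm	
18S	100	A	Am	
18S	106	U	Y	snR44
18S	132	C	Cm	
18S	235	A	Am	
18S	246	U	Y	
18S	365	G	Gm	
18S	436	A	Am	snR87
18S	562	U	Y	
18S	609	G	Gm	
18S	632	U	Y	snR161
18S	759	U	Y	snR80
18S	766	U	Y	snR161
18S	778	A	Am	
18S	809	U	Y	
18S	897	G	Gm	
18S	915	U	Y	
18S	974	A	Am	snR54
18S	999	U	Y	snR31
18S	1191	U	m1acp3Y	snR35
18S	1206	A	Am	
18S	1240	G	Gm	
18S	1253	C	Cm	
18S	1269	U	Um	snR55
18S	1271	G	Gm	
18S	1280	C	ac4C	snR4
18S	1290	U	Y	snR83
18S	1315	U	Y	
18S	1341	C	Cm	
18S	1415	U	Y	snR83
18S	1440	G	Gm	
18S	1468	U	Y	
18S	1639	C	Cm	snR70
18S	1684	U	Y	
18S	1718	G	Gm	
18S	1773	C	ac4C	snR45
18S	1782	A	m62A	Dim1
25S	33	U	Y	
25S	61	A	Am	
25S	97	G	Gm	
25S	116	C	Cm	
25S	175	G	Gm	
25S	189	A	Am	
25S	211	G	Gm	
25S	221	G	Gm	
25S	261	G	Gm	
25S	275	A	Am	
25S	350	A	Am	
25S	360	A	Am	
25S	461	C	Cm	
25S	497	G	Gm	
25S	630	C	Cm	
25S	667	U	Y	
25S	745	C	Cm	
25S	817	A	Am	snR60
25S	846	A	Am	
25S	908	G	Gm	snR60
25S	922	G	Gm	
25S	987	G	Gm	
25S	1036	G	Gm	
25S	1296	C	Cm	
25S	1367	A	Am	
25S	1415	A	Am	
25S	1437	C	Cm	U24
25S	1449	A	Am	U24
25S	1450	G	Gm	U24
25S	1529	G	Gm	
25S	1561	A	Am	
25S	1627	G	Gm	
25S	1687	U	Y	
25S	1785	C	Cm	
25S	1825	A	Am	
25S	1867	G	Gm	
25S	1889	G	Gm	
25S	1963	G	Gm	
25S	2004	C	Cm	
25S	2070	G	Gm	
25S	2087	A	Am	
25S	2107	G	Gm	
25S	2144	U	Y	
25S	2159	C	Cm	
25S	2221	U	Y	
25S	2243	U	Y	
25S	2262	U	Y	
25S	2282	C	Cm	
25S	2295	G	Gm	
25S	2369	U	Y	
25S	2382	A	Am	
25S	2417	G	Gm	
25S	2464	U	Y	
25S	2563	U	Y	
25S	2578	C	Cm	
25S	2590	G	Gm	
25S	2619	G	Gm	snR67
25S	2632	A	Am	
25S	2660	A	Am	
25S	2724	U	Um	snR67
25S	2782	U	Y	
25S	2799	C	Cm	
25S	2873	C	Cm	
25S	2921	U	Um	snR52
25S	2922	G	Gm	Spb1
25S	2923	U	Y	snR10
25S	2996	U	Y	
25S	3071	U	Y	
25S	3214	G	Gm	
25S	3246	C	Cm	
25S	3325	U	Y	
25S	3350	C	Cm	
25S	3368	G	Gm	
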