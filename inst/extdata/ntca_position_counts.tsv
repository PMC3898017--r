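replicon	size_kb	regions	genes	upstream	internal	downstream
chromosome	6413	2143	1939	802	1548	74
alpha	408	145	103	37	103	5
beta	187	86	66	16	71	0
delta	55.4	12	10	2	10	0
epsilon	40.3	10	9	3	7	0
gamma	102	28	26	5	23	0
zeta	5.6	0	0	0	0	0
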