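set_id	description	a	b	c	d
2q34	chromosome region 2q34	5	162	24	30139
10p15	chromosome region 10p15	5	162	55	30108
18q11	chromosome region 18q11	4	163	46	30117
3q26	chromosome region 3q26	5	162	105	30058
8p23	chromosome region 8p23	6	161	174	29989
3p21	chromosome region 3p21	7	160	251	29912
3q27	chromosome region 3q27	4	163	72	30091
22q12	chromosome region 22q12	5	162	142	30021
Xq13	chromosome region Xq13	4	163	100	30063
2q36	chromosome region 2q36	3	164	51	30112
10p11	chromosome region 10p11	3	164	62	30101
10p12	chromosome region 10p12	3	164	63	30100
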