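>EBOX_CAGCTG_SYNTH
148	122	116	114
497	1	1	1
1	497	1	1
495	2	2	1
1	1	497	1
1	497	1	1
1	1	1	497
1	1	497	1
144	118	121	117
126	125	123	126
>EBOX_CACGTG_SYNTH
139	121	126	114
496	2	1	1
1	496	1	2
495	2	2	1
1	1	497	1
1	1	1	497
1	1	497	1
125	127	124	124
>AT_RICH_SYNTH
370	45	44	41
360	47	47	46
44	42	46	368
365	45	45	45
46	42	44	368
369	44	43	44
43	45	44	368
361	46	47	46
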