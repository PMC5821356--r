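deme_row	deme_col	n_individuals	name
1	2	10	pop01
4	2	10	pop02
7	2	10	pop03
10	2	10	pop04
1	9	10	pop05
4	9	10	pop06
7	9	10	pop07
10	9	10	pop08
1	15	10	pop09
4	15	10	pop10
7	15	10	pop11
10	15	10	pop12
1	22	10	pop13
4	22	10	pop14
7	22	10	pop15
10	22	10	pop16
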