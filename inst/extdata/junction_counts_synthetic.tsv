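donor_exon	acceptor_exon	count
1	2	380
2	3	399
3	4	339
4	5	358
5	6	386
6	7	365
7	9	187
9	10	386
10	11	362
11	12	343
12	13	365
13	14	362
14	15	396
7	8	170
8	9	177
11	13	18
4	6	7
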