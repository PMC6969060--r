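#chrom	arm	start	end
1	1p	0	125000000
1	1q	125000000	249000000
2	2p	0	93000000
2	2q	93000000	243000000
3	3p	0	91000000
3	3q	91000000	198000000
4	4p	0	50000000
4	4q	50000000	191000000
5	5p	0	48000000
5	5q	48000000	181000000
6	6p	0	61000000
6	6q	61000000	171000000
7	7p	0	60000000
7	7q	60000000	159000000
8	8p	0	45000000
8	8q	45000000	146000000
9	9p	0	49000000
9	9q	49000000	141000000
10	10p	0	40000000
10	10q	40000000	136000000
11	11p	0	53000000
11	11q	53000000	135000000
12	12p	0	36000000
12	12q	36000000	134000000
13	13p	0	18000000
13	13q	18000000	115000000
14	14p	0	17000000
14	14q	17000000	107000000
15	15p	0	19000000
15	15q	19000000	103000000
16	16p	0	37000000
16	16q	37000000	90000000
17	17p	0	24000000
17	17q	24000000	81000000
18	18p	0	17000000
18	18q	17000000	78000000
19	19p	0	26000000
19	19q	26000000	59000000
20	20p	0	28000000
20	20q	28000000	63000000
21	21p	0	13000000
21	21q	13000000	48000000
22	22p	0	15000000
22	22q	15000000	51000000
X	Xp	0	61000000
X	Xq	61000000	155000000
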