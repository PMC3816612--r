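label	lo	hi	n_unigenes	n_ests
1	1	1	33322	33322
2	2	2	22758	45516
3	3	3	7451	22353
4	4	4	5668	22672
5	5	5	3023	15115
6	6	6	2446	14676
7	7	7	1661	11627
8	8	8	1306	10448
9	9	9	1044	9396
10	10	10	851	8510
11-30	11	30	4710	78071
31-50	31	50	649	24663
51-70	51	70	140	8220
71-90	71	90	33	2593
91-110	91	110	8	800
>110	111	Inf	13	3039
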