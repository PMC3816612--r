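margin	key	count
nt_type	di	5918
nt_type	tri	6651
nt_type	tetra	170
nt_type	penta	63
nt_type	hexa	50
nt_type	compound	718
repeats	5	4117
repeats	6	3959
repeats	7	1992
repeats	8	1067
repeats	9	602
repeats	10	340
class	TC/GA	2440
class	AG/CT	2384
class	TCT/AGA	841
class	GAA/TTC	776
class	CTT/AAG	711
class	GAT/ATC	468
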