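pairs	count
A:G,C:T	15029
A:C	2433
A:T	2828
C:G	2276
G:T	2514
T:-	1288
A:-	1172
C:-	611
G:-	607
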