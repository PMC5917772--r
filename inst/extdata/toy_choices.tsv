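run	trial	chosen_id	reward
1	1	N1	1
1	2	N2	0
1	3	NA	0
1	4	F1	1
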