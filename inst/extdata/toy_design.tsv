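# n_runs=1
# trials_per_run=4
# n_options=3
# replacement_fraction=0.5
# pool_size=6
# n_prefamiliarized=3
# reward_prob_values=0.2,0.33,0.46
# reward_magnitude=1
# min_replacement_gap=2
# balance_runs=TRUE
run	trial	img1	img2	img3	replacement	introduced_id
1	1	F1	N1	F2	0	NA
1	2	F1	N1	N2	1	N2
1	3	F1	N1	N2	0	NA
1	4	F1	F3	N2	1	F3
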