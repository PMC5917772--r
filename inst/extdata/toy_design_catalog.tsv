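image_id	prefamiliarized	reward_prob
F1	TRUE	0.46
F2	TRUE	0.2
F3	TRUE	0.33
N1	FALSE	0.33
N2	FALSE	0.46
N3	FALSE	0.2
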