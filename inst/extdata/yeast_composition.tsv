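statistic	value
n_proteins	2497
n_only_positive_proteins	76
n_only_negative_proteins	280
n_mixed_proteins	2141
n_interactions_approx	11200
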