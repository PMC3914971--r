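quantity	value
n_positive	208
n_negative	93
sensitivity	0.9567
specificity	0.6452
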