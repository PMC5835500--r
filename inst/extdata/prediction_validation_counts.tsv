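dataset	alphabet	n_total	n_matched
predicted	general	229	216
non_predicted	general	642	378
predicted	encoded	229	195
non_predicted	encoded	642	397
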