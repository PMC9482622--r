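{"n":120,"prevalence":0.0916666666666667,"n_missing":107,"use_counts":[55,33,14,8,10]}
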