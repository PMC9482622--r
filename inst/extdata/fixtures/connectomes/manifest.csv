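subject,file
1,subject_001.csv
2,subject_002.csv
3,subject_003.csv
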