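node,module
1,1
2,1
3,1
4,1
5,2
6,2
7,2
8,2
9,3
10,3
11,3
12,3
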