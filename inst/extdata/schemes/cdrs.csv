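definition,role,cdr,first,last
kabat,L,L1,24,34
kabat,L,L2,50,56
kabat,L,L3,89,97
kabat,H,H1,31,35
kabat,H,H2,50,65
kabat,H,H3,95,102
chothia,L,L1,26,32
chothia,L,L2,50,52
chothia,L,L3,91,96
chothia,H,H1,26,32
chothia,H,H2,52,56
chothia,H,H3,96,101
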