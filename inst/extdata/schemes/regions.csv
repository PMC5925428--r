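scheme,role,region,first,last,anchor
kabat,L,L1,24,34,27
kabat,L,L2,50,56,54
kabat,L,L3,89,97,95
kabat,H,H1,31,35,35
kabat,H,H2,50,65,52
kabat,H,H3,95,102,100
chothia,L,L1,24,34,30
chothia,L,L2,50,56,54
chothia,L,L3,89,97,95
chothia,H,H1,31,35,31
chothia,H,H2,50,65,52
chothia,H,H3,95,102,100
martin,L,L1,24,34,30
martin,L,L2,50,56,54
martin,L,L3,89,97,95
martin,H,H1,31,35,31
martin,H,H2,50,65,52
martin,H,H3,95,102,100
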