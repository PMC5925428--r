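idx,label
1,1
2,2
3,3
4,4
5,5
6,6
7,7
8,8
9,9
10,10
11,11
12,12
13,13
14,14
15,15
16,16
17,17
18,18
19,19
20,20
21,21
22,22
23,23
24,24
25,25
26,26
27,27
28,28
29,29
30,30
31,31
32,32
33,33
34,34
35,35
36,36
37,37
38,38
39,39
40,40
41,41
42,42
43,43
44,44
45,45
46,46
47,47
48,48
49,49
50,50
51,51
52,52
53,53
54,54
55,55
56,56
57,57
58,58
59,59
60,60
61,61
62,62
63,63
64,64
65,65
66,66
67,67
68,68
69,69
70,70
71,71
72,72
73,73
74,74
75,75
76,76
77,77
78,78
79,79
80,80
81,81
82,82
83,82A
84,82B
85,82C
86,83
87,84
88,85
89,86
90,87
91,88
92,89
93,90
94,91
95,92
96,93
97,94
98,95
99,96
100,97
101,98
102,99
103,100
104,101
105,102
106,103
107,104
108,105
109,106
110,107
111,108
112,109
113,110
114,111
115,112
116,113
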