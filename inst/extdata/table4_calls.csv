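sample_id,assay,pork,chicken,beef
1,mpcr,-,+,-
2,mpcr,-,+,-
3,mpcr,+,-,-
4,mpcr,+,-,+
5,mpcr,+,-,+
6,mpcr,+,-,+
7,mpcr,+,-,+
8,mpcr,+,-,+
9,mpcr,+,-,+
10,mpcr,+,-,+
11,mpcr,+,-,+
12,mpcr,+,-,+
13,mpcr,+,-,-
14,mpcr,+,-,-
15,mpcr,+,-,-
16,mpcr,+,-,-
17,mpcr,+,-,-
18,mpcr,+,-,+
19,mpcr,+,-,+
20,mpcr,+,-,+
21,mpcr,-,+,-
22,mpcr,+,-,-
23,mpcr,+,+,+
24,mpcr,-,+,-
25,mpcr,+,-,-
26,mpcr,+,+,+
27,mpcr,+,+,-
1,mqpcr,-,+,-
2,mqpcr,-,+,-
3,mqpcr,+,-,-
4,mqpcr,+,-,+
5,mqpcr,+,-,+
6,mqpcr,+,-,+
7,mqpcr,+,-,+
8,mqpcr,+,-,+
9,mqpcr,+,-,+
10,mqpcr,+,-,+
11,mqpcr,+,-,+
12,mqpcr,+,-,+
13,mqpcr,+,-,-
14,mqpcr,+,-,-
15,mqpcr,+,-,-
16,mqpcr,+,-,-
17,mqpcr,+,-,-
18,mqpcr,+,-,+
19,mqpcr,+,-,+
20,mqpcr,+,-,+
21,mqpcr,+,+,-
22,mqpcr,+,-,-
23,mqpcr,+,+,-
24,mqpcr,+,+,-
25,mqpcr,+,-,-
26,mqpcr,+,+,-
27,mqpcr,+,+,+
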