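sample_id,product_type,pork,chicken,beef,pork_pct,chicken_pct,beef_pct,max_fat_pct
1,ham,-,+,-,NA,92,NA,1.5
2,ham,-,+,-,NA,60,NA,1.5
3,ham,+,-,-,95,NA,NA,10
4,sausage,+,-,+,16,NA,35,40
5,sausage,+,-,+,40,NA,10,40
6,sausage,+,-,+,62,NA,23,40
7,sausage,+,-,+,40,NA,10,34
8,sausage,+,-,+,54,NA,26,44
9,luncheon,+,-,+,NA,NA,NA,40
10,sausage,+,-,+,16,NA,35,45
11,sausage,+,-,+,17,NA,26,NA
12,sausage,+,-,+,17.5,NA,38.5,45
13,natural_juices,+,-,-,70,NA,NA,33
14,luncheon,+,-,-,79,NA,NA,30
15,natural_juices,+,-,-,92,NA,NA,NA
16,natural_juices,+,-,-,70,NA,NA,40
17,natural_juices,+,-,-,70,NA,NA,30
18,sausage,+,-,+,33,NA,22,NA
19,sausage,+,-,+,71,NA,16,45
20,sausage,+,-,+,43,NA,17,45
21,luncheon,+,+,-,48,NA,NA,40
22,natural_juices,+,-,-,30,NA,NA,NA
23,luncheon,+,+,-,18,32,NA,30
24,luncheon,+,+,-,35,30,NA,25
25,luncheon,+,-,-,71,NA,NA,40
26,luncheon,+,+,-,31,39,NA,26
27,natural_juices,+,+,+,NA,NA,70,27
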