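lesion_id,patient_id,age,gender,body_site,superficial,nodular,infiltrative,ulceration,any_tls,primary_tls
1,1,43,F,trunk,1,0,0,1,0,0
2,2,73,F,trunk,0,1,0,1,0,0
3,2,73,F,trunk,0,1,0,1,1,0
4,3,88,F,head_neck,0,1,0,0,1,1
5,4,64,F,head_neck,1,0,0,1,0,0
6,5,71,M,head_neck,0,1,0,0,1,1
7,6,66,M,head_neck,1,1,0,1,1,0
8,7,75,M,extremity,0,1,0,1,1,0
9,8,66,M,extremity,1,0,0,1,0,0
10,8,66,M,trunk,1,1,0,1,0,0
11,8,66,M,head_neck,0,1,0,1,1,1
12,8,66,M,head_neck,0,1,0,1,0,0
13,8,66,M,head_neck,1,0,0,1,1,1
14,9,83,F,head_neck,0,1,1,0,0,0
15,10,59,M,trunk,0,1,0,0,1,1
16,10,59,M,trunk,0,1,0,0,1,0
17,11,81,M,head_neck,0,1,0,1,0,0
18,12,74,F,trunk,0,1,0,0,1,1
19,12,74,F,trunk,0,1,0,1,0,0
20,13,NA,unknown,head_neck,1,1,1,1,1,1
21,14,72,M,head_neck,0,1,1,1,1,1
22,15,90,M,head_neck,0,1,0,1,1,0
23,16,51,M,trunk,1,1,0,1,1,0
24,17,64,M,extremity,1,1,0,1,1,1
25,18,62,M,head_neck,0,1,0,1,0,0
26,18,62,M,head_neck,0,1,1,1,1,1
27,19,53,F,head_neck,0,1,0,0,1,0
28,20,80,F,head_neck,0,0,1,1,0,0
29,21,68,M,trunk,0,1,0,0,1,0
30,22,54,M,trunk,1,1,0,0,1,1
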