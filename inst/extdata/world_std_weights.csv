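age_lo,age_hi,weight
0,5,12000
5,10,10000
10,15,9000
15,20,9000
20,25,8000
25,30,8000
30,35,6000
35,40,6000
40,45,6000
45,50,6000
50,55,5000
55,60,4000
60,65,4000
65,70,3000
70,75,2000
75,80,1000
80,85,500
85,90,500
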