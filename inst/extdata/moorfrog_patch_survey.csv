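patch,n_counted,n_sampled,n_target,pct_target,ld_nb,ld_lo,ld_hi,sib_nb,sib_lo,sib_hi
HK1,NA,1,1,NA,NA,NA,NA,NA,NA,NA
01,13,13,13,100,16.1,10.3,28.0,26,14,52
02,70,31,3,10,6.4,2.4,32.7,7,2,41
1,85,9,3,3,2.9,2.1,6.9,10,4,Inf
10,37,17,17,100,31.8,21.7,51.5,29,17,54
11,16,12,12,100,24.6,16.8,40.2,15,7,34
13,47,18,16,89,29.8,20.9,46.1,31,18,55
14,35,14,14,100,22.3,14.7,37.7,24,13,47
16,60,37,10,27,21,12.9,41.6,18,10,39
17,35,21,7,33,8.2,5.2,13.0,17,9,39
18,51,51,50,98,54.0,40.7,74.1,95,69,129
19,25,21,21,100,48.7,31.5,88.6,33,20,56
20,4,4,4,100,2.8,2.0,7.0,9,4,28
21,25,18,8,41,15,9.5,26.5,17,8,41
22a,100,13,12,92,55.7,31.1,172.2,19,10,39
22b,70,17,16,94,31.0,22.0,47.1,29,17,51
22c,38,15,15,100,18.5,13.2,27.2,36,20,71
24,500,0,0,0,NA,NA,NA,NA,NA,NA
25,50,25,25,100,41.6,32.3,55.8,45,29,69
3,14,14,14,100,19.6,12.7,33.6,28,14,60
30,42,36,0,0,NA,NA,NA,NA,NA,NA
31,50,19,18,95,34.8,23.3,58.1,38,24,64
32,3,3,3,3,16.9,3.8,Inf,5,2,32
4,40,21,21,100,40.3,24.5,80.5,41,26,68
5,9,9,9,100,38.3,18.3,278.8,12,6,28
6,85,41,41,100,75.4,50.2,128.2,64,46,95
7,17,13,13,100,21.2,15.6,30.3,22,12,43
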