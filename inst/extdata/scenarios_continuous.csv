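scenario,dose,mean,sd,is_mtd,target,n_max
1,1,0.1,0.05,1,0.1,15
1,2,0.15,0.1,0,0.1,15
1,3,0.2,0.15,0,0.1,15
1,4,0.25,0.2,0,0.1,15
1,5,0.3,0.25,0,0.1,15
1,6,0.35,0.3,0,0.1,15
2,1,0.1,0.05,0,0.15,60
2,2,0.15,0.1,1,0.15,60
2,3,0.2,0.15,0,0.15,60
2,4,0.25,0.2,0,0.15,60
2,5,0.3,0.25,0,0.15,60
2,6,0.35,0.3,0,0.15,60
3,1,0.1,0.05,0,0.2,60
3,2,0.15,0.1,0,0.2,60
3,3,0.2,0.15,1,0.2,60
3,4,0.25,0.2,0,0.2,60
3,5,0.3,0.25,0,0.2,60
3,6,0.35,0.3,0,0.2,60
4,1,0.1,0.05,0,0.25,60
4,2,0.15,0.1,0,0.25,60
4,3,0.2,0.15,0,0.25,60
4,4,0.25,0.2,1,0.25,60
4,5,0.3,0.25,0,0.25,60
4,6,0.35,0.3,0,0.25,60
5,1,0.1,0.05,0,0.3,60
5,2,0.15,0.1,0,0.3,60
5,3,0.2,0.15,0,0.3,60
5,4,0.25,0.2,0,0.3,60
5,5,0.3,0.25,1,0.3,60
5,6,0.35,0.3,0,0.3,60
6,1,0.1,0.05,0,0.35,60
6,2,0.15,0.1,0,0.35,60
6,3,0.2,0.15,0,0.35,60
6,4,0.25,0.2,0,0.35,60
6,5,0.3,0.25,0,0.35,60
6,6,0.35,0.3,1,0.35,60
7,1,0.1,0.05,0,0.2,100
7,2,0.15,0.1,0,0.2,100
7,3,0.2,0.15,1,0.2,100
7,4,0.25,0.2,0,0.2,100
7,5,0.3,0.25,0,0.2,100
7,6,0.35,0.3,0,0.2,100
8,1,0.1,0.05,0,0.25,100
8,2,0.15,0.1,0,0.25,100
8,3,0.2,0.15,0,0.25,100
8,4,0.25,0.2,1,0.25,100
8,5,0.3,0.25,0,0.25,100
8,6,0.35,0.3,0,0.25,100
9,1,0.1,0.05,0,0.3,100
9,2,0.15,0.1,0,0.3,100
9,3,0.2,0.15,0,0.3,100
9,4,0.25,0.2,0,0.3,100
9,5,0.3,0.25,1,0.3,100
9,6,0.35,0.3,0,0.3,100
10,1,0.1,0.05,0,0.35,100
10,2,0.15,0.1,0,0.35,100
10,3,0.2,0.15,0,0.35,100
10,4,0.25,0.2,0,0.35,100
10,5,0.3,0.25,0,0.35,100
10,6,0.35,0.3,1,0.35,100
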