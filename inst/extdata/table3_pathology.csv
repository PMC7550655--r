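quantity,group,timepoint,mean,sd,n
HIF1a,A,week3,83.1,10.8,8
HIF1a,B,week3,68.6,7.9,8
HIF1a,C,week3,60.5,8.3,8
HIF1a,D,week3,39.3,5.7,8
Ki67,A,week3,68.5,6.0,8
Ki67,B,week3,54.6,5.7,8
Ki67,C,week3,47.9,5.1,8
Ki67,D,week3,35.1,5.9,8
TUNEL,A,week3,25.6,5.9,8
TUNEL,B,week3,50.8,7.6,8
TUNEL,C,week3,56.9,9.1,8
TUNEL,D,week3,75.1,8.1,8
PTEN,A,week3,26.1,5.4,8
PTEN,B,week3,44.1,5.7,8
PTEN,C,week3,51.8,6.7,8
PTEN,D,week3,79.0,9.6,8
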