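quantity,group,timepoint,mean,sd,n
volume,A,base,217.5,60.1,8
volume,A,week1,436.3,59.6,8
volume,A,week2,702.5,42.9,8
volume,A,week3,1039.8,93.9,8
volume,B,base,226.4,38.9,8
volume,B,week1,360.6,45.6,8
volume,B,week2,522.0,69.2,8
volume,B,week3,792.4,72.8,8
volume,C,base,226.0,45.3,8
volume,C,week1,380.5,45.1,8
volume,C,week2,588.1,53.4,8
volume,C,week3,757.6,60.6,8
volume,D,base,226.9,48.3,8
volume,D,week1,311.1,41.9,8
volume,D,week2,377.5,56.9,8
volume,D,week3,547.4,68.0,8
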