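table,scope,quantity,group,F
1,time-within-group,volume,A,225.693
1,time-within-group,volume,B,138.571
1,time-within-group,volume,C,163.686
1,time-within-group,volume,D,49.422
2,time-within-group,D,A,2.112
2,time-within-group,D,B,88.564
2,time-within-group,D,C,64.248
2,time-within-group,D,D,227.398
2,time-within-group,Dstar,A,12.594
2,time-within-group,Dstar,B,3.643
2,time-within-group,Dstar,C,2.792
2,time-within-group,Dstar,D,5.307
2,time-within-group,f,A,14.785
2,time-within-group,f,B,8.778
2,time-within-group,f,C,6.66
2,time-within-group,f,D,0.479
2,time-within-group,R2star,A,15.297
2,time-within-group,R2star,B,5.421
2,time-within-group,R2star,C,11.17
2,time-within-group,R2star,D,136.315
3,group-at-final,HIF1a,NA,37.969
3,group-at-final,Ki67,NA,47.414
3,group-at-final,TUNEL,NA,55.906
3,group-at-final,PTEN,NA,77.738
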