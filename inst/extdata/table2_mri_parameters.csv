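quantity,group,timepoint,mean,sd,n
D,A,base,0.556,0.024,8
D,A,week1,0.564,0.017,8
D,A,week2,0.546,0.029,8
D,A,week3,0.536,0.022,8
D,B,base,0.562,0.030,8
D,B,week1,0.628,0.023,8
D,B,week2,0.699,0.028,8
D,B,week3,0.800,0.039,8
D,C,base,0.555,0.019,8
D,C,week1,0.608,0.031,8
D,C,week2,0.695,0.032,8
D,C,week3,0.778,0.050,8
D,D,base,0.566,0.026,8
D,D,week1,0.762,0.026,8
D,D,week2,0.868,0.021,8
D,D,week3,0.930,0.043,8
Dstar,A,base,8.53,0.57,8
Dstar,A,week1,8.87,0.82,8
Dstar,A,week2,9.81,0.61,8
Dstar,A,week3,10.25,0.52,8
Dstar,B,base,8.49,0.50,8
Dstar,B,week1,8.43,0.60,8
Dstar,B,week2,8.79,0.68,8
Dstar,B,week3,9.45,0.91,8
Dstar,C,base,8.59,0.44,8
Dstar,C,week1,8.47,0.58,8
Dstar,C,week2,8.91,0.52,8
Dstar,C,week3,9.07,0.27,8
Dstar,D,base,8.53,0.45,8
Dstar,D,week1,7.54,0.48,8
Dstar,D,week2,7.87,0.60,8
Dstar,D,week3,8.04,0.50,8
f,A,base,16.75,0.95,8
f,A,week1,17.71,0.83,8
f,A,week2,18.60,0.74,8
f,A,week3,19.15,0.50,8
f,B,base,16.69,0.69,8
f,B,week1,17.45,0.71,8
f,B,week2,17.51,0.73,8
f,B,week3,18.60,0.86,8
f,C,base,16.74,0.79,8
f,C,week1,17.11,0.55,8
f,C,week2,18.01,0.83,8
f,C,week3,18.25,0.94,8
f,D,base,16.70,0.51,8
f,D,week1,16.59,0.65,8
f,D,week2,16.81,0.88,8
f,D,week3,16.96,0.51,8
R2star,A,base,24.74,0.61,8
R2star,A,week1,25.44,0.75,8
R2star,A,week2,26.41,0.65,8
R2star,A,week3,26.98,0.85,8
R2star,B,base,24.79,0.64,8
R2star,B,week1,23.46,1.14,8
R2star,B,week2,22.86,1.50,8
R2star,B,week3,22.58,1.33,8
R2star,C,base,24.60,1.08,8
R2star,C,week1,23.00,1.87,8
R2star,C,week2,22.04,1.18,8
R2star,C,week3,21.11,0.55,8
R2star,D,base,24.74,0.65,8
R2star,D,week1,21.41,0.81,8
R2star,D,week2,19.64,0.72,8
R2star,D,week3,17.30,0.84,8
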