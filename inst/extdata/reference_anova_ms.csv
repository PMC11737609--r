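source,df,FD1,FD2,FD3,ED,GY,AD,SD,PH,EH
Environment,1,585.14,1226.48,188.82,904.29,517.27,1370.63,1643.60,449354.88,66285.68
Rep(Env),2,11.15,0.70,0.47,1.91,84.25,86.92,120.55,2363.93,761.11
Hybrids,209,0.84,0.93,1.50,1.04,5.35,12.60,14.23,1339.47,715.07
GCA,20,3.99,4.16,8.40,6.33,26.50,102.27,106.97,8146.64,4740.95
SCA,189,0.53,0.62,0.83,0.48,3.14,3.12,4.42,648.26,299.01
HxE,209,0.69,0.63,0.86,0.47,2.64,1.74,2.86,366.30,159.28
GCAxE,20,1.18,1.97,2.84,1.91,8.48,2.78,5.22,544.96,160.24
SCAxE,189,0.61,0.46,0.67,0.32,2.06,1.63,2.62,324.74,152.39
Error,225,0.30,0.32,0.36,0.23,1.23,1.25,1.42,109.10,47.82
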