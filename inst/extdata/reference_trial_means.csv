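entry,is_check,GY,AD,PH,FD1,FD2,FD3,ED,ER
CKSBL10153/CKDHL0214,FALSE,8.16,58.71,273.92,3.87,5.46,4.39,1.96,5.33
CKSBL10039/CKSBL10060,FALSE,7.87,55.60,279.81,4.35,4.93,4.79,1.81,2.04
CKSBL10011/CLRCY039,FALSE,7.60,57.83,275.11,4.27,4.98,4.76,1.85,-0.43
CKDHL164271/CML338,FALSE,7.56,54.40,280.50,4.78,5.72,5.10,1.78,3.64
CKDHL0214/CLRCY039,FALSE,7.52,59.57,263.95,4.29,5.47,5.22,1.99,2.74
CKSBL10039/CKSBL10153,FALSE,7.51,58.25,289.92,3.87,4.03,3.61,2.00,12.00
CKSBL10043/CKSBL10060,FALSE,7.47,52.57,245.47,3.69,4.36,4.76,1.79,1.45
CKSBL10008/CML338,FALSE,7.42,54.30,281.35,2.91,3.59,3.35,2.01,2.04
CML560/CKSBL10008,FALSE,7.42,54.35,274.88,4.42,5.59,4.93,2.20,3.94
CKDHL0214/CML22,FALSE,7.41,58.39,263.14,4.63,4.95,4.72,2.38,3.17
CKSBL10008/CLRCY039,FALSE,7.26,60.58,272.28,4.11,4.53,4.20,1.78,2.17
CKSBL10153/CLRCY039,FALSE,7.17,61.18,278.15,3.72,4.55,3.81,1.73,-0.10
CKSBL10039/CLRCY039,FALSE,7.16,59.96,285.15,4.54,5.19,4.59,2.49,5.45
CKDHL0214/CML338,FALSE,7.14,55.26,275.24,4.36,5.25,4.63,2.01,3.39
CKSBL10039/CML338,FALSE,7.08,55.60,267.80,3.99,4.83,4.74,1.85,8.12
WE1101,TRUE,5.29,56.56,258.55,4.68,5.45,5.32,2.57,8.59
Duma43,TRUE,4.40,53.53,266.79,4.41,5.58,5.55,3.85,35.99
DK8031,TRUE,3.69,55.68,260.68,4.99,6.03,5.75,4.65,50.64
DH04,TRUE,2.97,58.01,254.36,5.03,6.32,6.07,3.31,40.83
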