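parent,GY,FD1,FD2,FD3,ED,AD,SD,PH,EH,ER
CKSBL10026,-0.63,-0.08,-0.11,-0.17,-0.15,-0.19,0.08,-4.03,5.72,-2.47
CKSPL10158,-0.71,0.31,0.41,0.50,0.04,-0.60,-1.41,-3.76,-10.20,0.48
CKSPL10007,-0.43,0.10,0.27,0.57,0.22,0.12,-0.10,9.45,-1.89,4.07
CKSBL10011,-0.01,-0.10,-0.09,-0.17,-0.22,-1.48,-1.42,-0.60,-4.22,-3.59
CKSBL10027,-0.87,-0.17,-0.20,-0.37,0.19,-0.32,0.28,-16.13,-7.24,2.45
CKSBL10039,0.68,-0.24,-0.22,-0.35,-0.11,0.52,0.71,13.87,6.26,-0.32
CKSBL10008,0.81,-0.15,-0.20,-0.07,-0.16,-0.68,-0.59,6.92,4.59,-4.02
CML560,-0.20,0.27,0.19,0.00,-0.02,-0.10,-1.14,-2.88,-1.04,-0.63
CKSBL10043,0.12,-0.35,-0.32,0.04,-0.22,-1.73,-0.71,-11.61,-14.42,-1.92
CKSBL10060,0.36,-0.02,-0.02,0.03,-0.25,-1.77,-1.64,-5.35,-1.10,-2.68
CKIR04005,0.06,-0.17,-0.15,-0.25,-0.04,-0.22,-0.35,-2.62,0.50,-0.76
CKSBL10153,1.11,-0.13,-0.21,-0.27,-0.21,1.49,1.17,15.55,13.15,-3.94
CKDHL0214,0.26,0.34,0.32,0.15,0.33,1.02,0.53,-5.77,-3.14,4.85
CKSBL10020,-1.07,-0.14,-0.22,-0.38,0.85,0.15,1.24,-11.95,-3.11,16.88
CKDHL121320,-0.26,0.31,0.07,-0.19,0.40,1.64,1.79,19.78,21.76,6.76
CLRCY039,0.99,-0.02,-0.02,-0.19,-0.30,2.73,2.56,8.71,4.34,-3.82
CKDHL166075,-0.06,-0.07,0.15,0.45,0.33,-0.49,-0.47,-10.50,-5.78,2.62
CKDHL164271,0.24,0.47,0.39,0.40,-0.18,-0.60,0.04,1.88,-0.12,-3.25
CKSPL10089,0.13,0.03,0.15,0.43,-0.17,-1.24,-1.94,13.52,-3.99,-2.38
CML22,-0.01,0.12,0.18,0.36,-0.26,0.62,0.09,-1.88,3.98,-5.46
CML71,-0.51,-0.33,-0.34,-0.51,-0.08,1.15,1.28,-12.64,-4.05,-2.88
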