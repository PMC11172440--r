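type,R,eps
CT,1.9080,0.1094
C,1.9080,0.0860
CA,1.9080,0.0860
N,1.8240,0.1700
N2,1.8240,0.1700
N3,1.8240,0.1700
O,1.6612,0.2100
O2,1.6612,0.2100
OH,1.7210,0.2104
S,2.0000,0.2500
SH,2.0000,0.2500
P,2.1000,0.2000
H,0.6000,0.0157
HO,0.0001,0.0000
HS,0.6000,0.0157
HC,1.4870,0.0157
H1,1.3870,0.0157
HA,1.4590,0.0150
Zn,1.1000,0.0125
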