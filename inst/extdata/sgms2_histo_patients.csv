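parameter,patient1,patient2
BV/TV,22.19,22.55
Tb.Th,134.71,91.83
Tb.N,1.65,2.46
Ct.Wi,0.78,0.41
Ct.Po,4.46,38.60
OV/BV,2.73,1.51
O.Th,4.1,4.22
OS/BS,50.33,21.31
Ob.S/BS,7.45,0.46
MS/BS,3.8,2.62
MAR,0.7,0.70
Aj.Ar,0.053,0.09
BFR/BS,9.73,6.73
BFR/BV,14.91,14.66
Mlt,77.38,48.78
ES/BS,8.67,16.25
Oc.S/BS,0.28,1.9
N.Oc/BS,0.1,0.48
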