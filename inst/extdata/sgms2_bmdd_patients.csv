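parameter,compartment,patient1,patient2
CaMean,cortical,22.39,21.27
CaPeak,cortical,23.40,22.01
CaWidth,cortical,4.33,4.51
CaLow,cortical,6.42,8.17
CaHigh,cortical,12.68,4.48
CaMean,trabecular,20.86,20.63
CaPeak,trabecular,22.0,21.49
CaWidth,trabecular,5.89,4.85
CaLow,trabecular,11.93,10.54
CaHigh,trabecular,4.71,2.22
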