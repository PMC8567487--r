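parameter,mean,sd,source
CaMean,22.2,0.45,roschger_adult_trabecular
CaPeak,22.94,0.39,roschger_adult_trabecular
CaWidth,3.35,0.34,roschger_adult_trabecular
CaLow,4.93,1.57,roschger_adult_trabecular
CaHigh,5.55,3.32,roschger_adult_trabecular
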