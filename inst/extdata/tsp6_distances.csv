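"V1","V2","V3","V4","V5","V6"
0,4,5.8309518948453,5.3851648071345,4.12310562561766,2.23606797749979
4,0,3.16227766016838,5.3851648071345,6.40312423743285,3.60555127546399
5.8309518948453,3.16227766016838,0,3.60555127546399,6.08276253029822,4.12310562561766
5.3851648071345,5.3851648071345,3.60555127546399,0,3.16227766016838,3.16227766016838
4.12310562561766,6.40312423743285,6.08276253029822,3.16227766016838,0,2.82842712474619
2.23606797749979,3.60555127546399,4.12310562561766,3.16227766016838,2.82842712474619,0
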