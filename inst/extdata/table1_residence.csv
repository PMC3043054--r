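shell,d_lo,d_hi,tau1,tau2,rel_rms_error
1,0.00,0.35,1.389,2670.862,0.742
2,0.35,0.60,3.611,212.193,0.663
3,0.60,0.85,1.388,22.131,0.164
4,0.85,1.10,1.072,14.341,0.057
5,1.10,1.35,0.969,13.516,0.269
6,1.35,1.60,1.145,13.774,0.183
7,1.60,1.85,1.631,15.502,0.123
8,1.85,2.10,1.876,14.695,0.223
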