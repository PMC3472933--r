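# GZP6 source No. 3 reference data: Monte Carlo dose-rate constant (reference table 3)
lambda_cGy_h_U,uncertainty
1.104,0.03
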