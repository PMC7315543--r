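((S1:0.04,(S2:0.03,S3:0.03):0.01):0.02,((S4:0.03,S5:0.03):0.02,S6:0.05):0.01);
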