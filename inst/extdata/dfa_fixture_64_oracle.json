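{"window_sizes":[4,8,16,32],"fluctuation":[0.382269608895591,0.586886618446601,0.806225495939022,0.993403204042668],"alpha":[0.459146826970427]}
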