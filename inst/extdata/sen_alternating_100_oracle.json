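{"sen":[0],"cm":[4704],"cm1":[4704]}
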