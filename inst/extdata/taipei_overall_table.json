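{"a": 106, "b": 33, "c": 110, "d": 29}
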