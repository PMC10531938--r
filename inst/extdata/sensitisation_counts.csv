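origin,n_collected,n_oviposited
homogeneous,40,7
fragmented,6,3
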