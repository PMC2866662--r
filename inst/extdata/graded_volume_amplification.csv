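reaction_volume_ul,n_wells,fraction_amplified
5,31,0.264
10,31,0.50
15,31,0.623
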