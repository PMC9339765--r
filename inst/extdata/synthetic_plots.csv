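plot_id,area,host_plants
A,916,137
B,807,121
C,2952,118
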