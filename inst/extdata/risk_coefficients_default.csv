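a_s,a_i,b_s,b_i,provenance
-0.0010,0.0400,-0.0003,0.0135,heatmort package defaults (representative warm-climate fit)
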