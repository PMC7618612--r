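exposure,n_exposed,n_events_exposed,n_reference,n_events_reference
moderate,4894,101,14041,251
severe,1121,31,14041,251
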