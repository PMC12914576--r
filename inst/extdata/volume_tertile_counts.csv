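group,n_patients
small,721
medium,723
large,720
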