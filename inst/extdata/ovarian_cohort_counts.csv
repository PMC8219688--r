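group,pcna_high,pcna_low
low_TUBG,38,19
high_TUBG,79,11
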