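consequence	n_sites
nonsense	23
missense_probably	213
missense_other	449
synonymous	429
utr_intron	738
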