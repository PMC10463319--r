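beverage	units_per_drink
red_wine	2
white_wine	2
beer_cider	2
spirits	1
fortified_wine	1
other	1.5
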