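sex,age,height_mean,height_sd
male,9,134.4,7
male,10,139.9,7
male,11,145.4,7
male,12,150.9,7
male,13,156.4,7
female,9,133.4,7
female,10,138.9,7
female,11,144.4,7
female,12,149.9,7
female,13,155.4,7
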