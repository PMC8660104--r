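species,mean_s,sd_s
mouse_synthetic,5.2,2.1
wolf_synthetic,12.5,9.8
dog_synthetic,24.0,18.5
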