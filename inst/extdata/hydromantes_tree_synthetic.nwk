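((H_genei:0.09,((H_flavus:0.03,H_supramontis:0.03):0.02,(H_sarrabusensis:0.035,H_imperialis:0.035):0.015):0.04):0.05,(H_italicus:0.07,(H_ambrosii:0.04,H_strinatii:0.04):0.03):0.05);
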