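site,total_nr,total_nisp
Uluzzo C,6280,612
Roccia San Sebastiano,1998,515
Riparo del Broion,12114,174
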