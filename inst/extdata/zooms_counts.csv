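site,tested,determined
Uluzzo C,46,21
Roccia San Sebastiano,55,42
Riparo del Broion,94,84
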