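site,taxon,order_group,nisp,group_nisp
Roccia San Sebastiano,Cervus elaphus,Ungulata,112,509
Uluzzo C,Vulpes vulpes,Carnivora,44,55
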