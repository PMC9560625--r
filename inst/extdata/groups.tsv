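group_name	member_taxon
Bos/Bison	Bos primigenius
Bos/Bison	Bison priscus
Ursus sp./Lynx lynx	Ursus sp.
Ursus sp./Lynx lynx	Felis sp.
Ursus sp./Lynx lynx	Lynx lynx
Caprinae/Cervidae	Cervus elaphus
Caprinae/Cervidae	Capreolus capreolus
Caprinae/Cervidae	Rupicapra rupicapra
Carnivora/Sus scrofa/Lepus sp.	Canis lupus
Carnivora/Sus scrofa/Lepus sp.	Vulpes vulpes
Carnivora/Sus scrofa/Lepus sp.	Ursus sp.
Carnivora/Sus scrofa/Lepus sp.	Felis sp.
Carnivora/Sus scrofa/Lepus sp.	Lynx lynx
Carnivora/Sus scrofa/Lepus sp.	Sus scrofa
Carnivora/Sus scrofa/Lepus sp.	Lepus sp.
Ungulata	Equus ferus
Ungulata	Sus scrofa
Ungulata	Cervus elaphus
Ungulata	Capreolus capreolus
Ungulata	Rupicapra rupicapra
Ungulata	Bos primigenius
Ungulata	Bison priscus
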