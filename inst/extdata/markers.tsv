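taxon	series	mono_mz	diagnostic
Cervus elaphus	A	1180.7	TRUE
Cervus elaphus	B	1550.8	TRUE
Cervus elaphus	C	2883.3	TRUE
Cervus elaphus	F	2163.0	FALSE
Cervus elaphus	G	3033.0	TRUE
Capreolus capreolus	A	1166.7	TRUE
Capreolus capreolus	B	1580.9	TRUE
Capreolus capreolus	C	2871.2	TRUE
Capreolus capreolus	F	2163.0	FALSE
Capreolus capreolus	G	3033.0	TRUE
Rupicapra rupicapra	A	1196.8	TRUE
Rupicapra rupicapra	B	1572.9	TRUE
Rupicapra rupicapra	C	2899.5	TRUE
Rupicapra rupicapra	F	2163.0	FALSE
Rupicapra rupicapra	G	3033.0	TRUE
Sus scrofa	A	1225.8	TRUE
Sus scrofa	B	1593.9	TRUE
Sus scrofa	C	2919.5	TRUE
Sus scrofa	D	1453.7	TRUE
Sus scrofa	F	2163.0	FALSE
Equus ferus	A	1211.7	TRUE
Equus ferus	B	1605.9	TRUE
Equus ferus	C	2935.5	TRUE
Equus ferus	F	2163.0	FALSE
Bos primigenius	A	1192.7	TRUE
Bos primigenius	B	1427.8	TRUE
Bos primigenius	C	2131.1	TRUE
Bos primigenius	F	2163.0	FALSE
Bos primigenius	G	3093.0	TRUE
Bison priscus	A	1192.7	TRUE
Bison priscus	B	1427.8	TRUE
Bison priscus	C	2131.1	TRUE
Bison priscus	F	2163.0	FALSE
Bison priscus	G	3093.0	TRUE
Canis lupus	A	1253.8	TRUE
Canis lupus	B	1617.9	TRUE
Canis lupus	D	1453.7	TRUE
Vulpes vulpes	A	1267.8	TRUE
Vulpes vulpes	B	1631.9	TRUE
Vulpes vulpes	D	1453.7	TRUE
Lepus sp.	A	1279.8	TRUE
Lepus sp.	B	1645.9	TRUE
Lepus sp.	D	1453.7	TRUE
Ursus sp.	A	1241.7	TRUE
Ursus sp.	B	1563.8	TRUE
Ursus sp.	C	2853.4	TRUE
Ursus sp.	D	1453.7	TRUE
Felis sp.	A	1241.7	TRUE
Felis sp.	B	1563.8	TRUE
Felis sp.	C	2853.4	TRUE
Felis sp.	D	1453.7	TRUE
Lynx lynx	A	1241.7	TRUE
Lynx lynx	B	1563.8	TRUE
Lynx lynx	C	2853.4	TRUE
Lynx lynx	D	1453.7	TRUE
Mammalia	P1105	1105.6	FALSE
Mammalia	P1706	1706.7	FALSE
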