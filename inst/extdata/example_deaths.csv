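tod,icd_group,age_y,gender
00:12,CA,64,1
02:45,PN,88,2
06:05,CA,71,1
06:30,IHD,79,2
08:51,OTH,55,1
10:00,PN,92,2
12:33,CA,68,2
14:07,OTH,47,1
15:59,IHD,84,1
18:20,PN,81,2
20:15,CA,73,1
20:44,IHD,77,2
22:38,OTH,59,2
23:59,PN,90,1
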