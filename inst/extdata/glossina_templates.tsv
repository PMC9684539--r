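template_id	genus	complex	species	subspecies	count	base_thickness	sex_offset	noise_scale	patches
austeni	Glossina	NA	austeni	NA	4	140	12	10	0.423:0.676:0.176:37;0.295:0.287:0.192:17
brevipalpis	Glossina	NA	brevipalpis	NA	13	154	12	10	0.531:0.204:0.1:7;0.443:0.55:0.104:157
calliginea	Glossina	NA	calliginea	NA	23	168	12	10	0.28:0.677:0.082:51;0.298:0.208:0.135:12;0.392:0.158:0.125:99
fusca_fusca	Glossina	NA	fusca	fusca	20	182	12	10	0.731:0.774:0.125:-22;0.338:0.597:0.097:55
fuscipes_fuscipes	Glossina	fuscipes	fuscipes	fuscipes	301	196	12	10	0.761:0.738:0.153:154;0.292:0.469:0.198:-14;0.283:0.581:0.103:95
fuscipes_quazensis	Glossina	fuscipes	fuscipes	quazensis	96	210	12	10	0.255:0.613:0.169:63;0.313:0.556:0.189:-34
haningtoni	Glossina	NA	haningtoni	NA	1	224	12	10	0.188:0.8:0.157:145;0.835:0.363:0.125:28
longipalpis	Glossina	NA	longipalpis	NA	30	238	12	10	0.568:0.673:0.192:34;0.592:0.442:0.106:-49;0.746:0.196:0.163:78
longipenis	Glossina	NA	longipenis	NA	4	252	12	10	0.798:0.152:0.153:65;0.174:0.587:0.125:45
medicorum	Glossina	NA	medicorum	NA	12	266	12	10	0.325:0.459:0.166:-11;0.266:0.284:0.108:121;0.431:0.4:0.141:-36
morsitans_centralis	Glossina	morsitans	morsitans	centralis	22	280	12	10	0.387:0.816:0.08:-50;0.202:0.587:0.168:-30;0.735:0.161:0.099:-27
morsitans_morsitans	Glossina	morsitans	morsitans	morsitans	146	294	12	10	0.267:0.522:0.121:-60;0.838:0.654:0.099:-21
morsitans_submorsitans	Glossina	morsitans	morsitans	submorsitans	30	308	12	10	0.169:0.658:0.167:-42;0.242:0.582:0.139:-16;0.876:0.189:0.135:83
nashi	Glossina	NA	nashi	NA	2	322	12	10	0.356:0.71:0.111:-10;0.523:0.773:0.104:-59
nigrofusca_nigrofusca	Glossina	NA	nigrofusca	nigrofusca	11	336	12	10	0.166:0.558:0.175:151;0.102:0.172:0.128:75;0.244:0.797:0.184:-31
pallicera_pallicera	Glossina	NA	pallicera	pallicera	14	350	12	10	0.151:0.262:0.143:150;0.25:0.523:0.114:135
pallidipes	Glossina	NA	pallidipes	NA	117	364	12	10	0.115:0.306:0.138:109;0.647:0.819:0.136:144
palpalis_gambiensis	Glossina	palpalis	palpalis	gambiensis	195	378	12	10	0.584:0.699:0.197:-29;0.866:0.616:0.098:137;0.801:0.626:0.124:147
palpalis_palpalis	Glossina	palpalis	palpalis	palpalis	620	392	12	10	0.201:0.792:0.114:112;0.79:0.271:0.116:-36;0.566:0.218:0.173:3
swynertoni	Glossina	NA	swynertoni	NA	3	406	12	10	0.125:0.685:0.093:153;0.486:0.671:0.189:47
tabaniformis	Glossina	NA	tabaniformis	NA	2	420	12	10	0.242:0.637:0.151:18;0.769:0.583:0.165:69;0.767:0.798:0.132:116
tachinoides	Glossina	NA	tachinoides	NA	94	434	12	10	0.892:0.601:0.166:76;0.737:0.533:0.192:58;0.539:0.379:0.107:100
vanhoofi	Glossina	NA	vanhoofi	NA	2	448	12	10	0.799:0.548:0.111:40;0.751:0.711:0.099:135;0.103:0.786:0.133:-43
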