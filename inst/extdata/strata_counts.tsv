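cohort	score	category	cases	controls
training	grs	0	251	775
training	grs	1	430	768
training	grs	2	590	761
training	grs	3	1060	773
training	smoke_grs	0	204	773
training	smoke_grs	1	337	767
training	smoke_grs	2	557	768
training	smoke_grs	3	1233	769
testing	grs	0	363	496
testing	grs	1	442	494
testing	grs	2	531	496
testing	grs	3	601	498
testing	smoke_grs	0	148	496
testing	smoke_grs	1	388	493
testing	smoke_grs	2	625	497
testing	smoke_grs	3	764	493
all	grs	0	536	1268
all	grs	1	944	1266
all	grs	2	1271	1264
all	grs	3	1517	1263
all	smoke_grs	0	390	1256
all	smoke_grs	1	728	1272
all	smoke_grs	2	1223	1260
all	smoke_grs	3	1915	1268
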