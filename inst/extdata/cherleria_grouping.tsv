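individual	population	taxon
BA231_1	BA231	baldaccii
BA231_2	BA231	baldaccii
BA231_3	BA231	baldaccii
BA231_4	BA231	baldaccii
BA231_5	BA231	baldaccii
BA232_1	BA232	baldaccii
BA232_2	BA232	baldaccii
BA232_3	BA232	baldaccii
BA232_4	BA232	baldaccii
BA232_5	BA232	baldaccii
CA217_1	CA217	capillacea
CA217_2	CA217	capillacea
CA217_3	CA217	capillacea
CA217_4	CA217	capillacea
CA217_5	CA217	capillacea
CA48_1	CA48	capillacea
CA48_2	CA48	capillacea
CA48_3	CA48	capillacea
CA48_4	CA48	capillacea
CA48_5	CA48	capillacea
CA64_1	CA64	capillacea
CA64_2	CA64	capillacea
CA64_3	CA64	capillacea
CA64_4	CA64	capillacea
CA64_5	CA64	capillacea
CA233_1	CA233	capillacea_albanian
CA233_2	CA233	capillacea_albanian
CA233_3	CA233	capillacea_albanian
CA233_4	CA233	capillacea_albanian
CA233_5	CA233	capillacea_albanian
DI230_1	DI230	dirphya
DI230_2	DI230	dirphya
DI230_3	DI230	dirphya
DI230_4	DI230	dirphya
DI230_5	DI230	dirphya
DO222_1	DO222	doerfleri
DO222_2	DO222	doerfleri
GA223_1	GA223	garckeana
GA223_2	GA223	garckeana
GA223_3	GA223	garckeana
GA223_4	GA223	garckeana
GA223_5	GA223	garckeana
GA224_1	GA224	garckeana
GA224_2	GA224	garckeana
GA224_3	GA224	garckeana
GA224_4	GA224	garckeana
GA226_1	GA226	garckeana
GA226_2	GA226	garckeana
GA226_3	GA226	garckeana
GA226_4	GA226	garckeana
GA226_5	GA226	garckeana
GA227_1	GA227	garckeana
GA227_2	GA227	garckeana
GA227_3	GA227	garckeana
GA227_4	GA227	garckeana
GA227_5	GA227	garckeana
GA228_1	GA228	garckeana
GA228_2	GA228	garckeana
GA228_3	GA228	garckeana
GA228_4	GA228	garckeana
GA228_5	GA228	garckeana
LN38_1	LN38	langii
LN38_2	LN38	langii
LN38_3	LN38	langii
LN38_4	LN38	langii
LN38_5	LN38	langii
LN39_1	LN39	langii
LN39_2	LN39	langii
LN39_3	LN39	langii
LN39_4	LN39	langii
LN39_5	LN39	langii
LN54_1	LN54	langii
LN54_2	LN54	langii
LN54_3	LN54	langii
LN54_4	LN54	langii
LN54_5	LN54	langii
LN56_1	LN56	langii
LN56_2	LN56	langii
LN56_3	LN56	langii
LN56_4	LN56	langii
LN56_5	LN56	langii
LN57_1	LN57	langii
LN57_2	LN57	langii
LN57_3	LN57	langii
LN57_4	LN57	langii
LN57_5	LN57	langii
LN58_1	LN58	langii
LN58_2	LN58	langii
LN58_3	LN58	langii
LN58_4	LN58	langii
LN58_5	LN58	langii
LN59_1	LN59	langii
LN59_2	LN59	langii
LN59_3	LN59	langii
LN59_4	LN59	langii
LN60_1	LN60	langii
LN60_2	LN60	langii
LN60_3	LN60	langii
LN60_4	LN60	langii
LN61_1	LN61	langii
LN61_2	LN61	langii
LN61_3	LN61	langii
LN61_4	LN61	langii
LN61_5	LN61	langii
LN71_1	LN71	langii
LN71_2	LN71	langii
LN71_3	LN71	langii
LN71_4	LN71	langii
LN71_5	LN71	langii
LN72_1	LN72	langii
LN72_2	LN72	langii
LN72_3	LN72	langii
LN74_1	LN74	langii
LN74_2	LN74	langii
LN74_3	LN74	langii
LN74_4	LN74	langii
LN74_5	LN74	langii
LN76_1	LN76	langii
LN76_2	LN76	langii
LN76_3	LN76	langii
LN76_4	LN76	langii
LN77_1	LN77	langii
LN77_2	LN77	langii
LN79_1	LN79	langii
LN79_2	LN79	langii
LN79_3	LN79	langii
LN79_4	LN79	langii
LN79_5	LN79	langii
LN80_1	LN80	langii
LN80_2	LN80	langii
LN80_3	LN80	langii
LN80_4	LN80	langii
LN80_5	LN80	langii
LL40_1	LL40	laricifolia_laricifolia
LL40_2	LL40	laricifolia_laricifolia
LL40_3	LL40	laricifolia_laricifolia
LL40_4	LL40	laricifolia_laricifolia
LL40_5	LL40	laricifolia_laricifolia
LL41_1	LL41	laricifolia_laricifolia
LL41_2	LL41	laricifolia_laricifolia
LL41_3	LL41	laricifolia_laricifolia
LL41_4	LL41	laricifolia_laricifolia
LL41_5	LL41	laricifolia_laricifolia
LL42_1	LL42	laricifolia_laricifolia
LL42_2	LL42	laricifolia_laricifolia
LL42_3	LL42	laricifolia_laricifolia
LL42_4	LL42	laricifolia_laricifolia
LL42_5	LL42	laricifolia_laricifolia
LL47_1	LL47	laricifolia_laricifolia
LL47_2	LL47	laricifolia_laricifolia
LL47_3	LL47	laricifolia_laricifolia
LL47_4	LL47	laricifolia_laricifolia
LL47_5	LL47	laricifolia_laricifolia
LL49_1	LL49	laricifolia_laricifolia
LL49_2	LL49	laricifolia_laricifolia
LL49_3	LL49	laricifolia_laricifolia
LL49_4	LL49	laricifolia_laricifolia
LL49_5	LL49	laricifolia_laricifolia
LL55_1	LL55	laricifolia_laricifolia
LL55_2	LL55	laricifolia_laricifolia
LL55_3	LL55	laricifolia_laricifolia
LL55_4	LL55	laricifolia_laricifolia
LL55_5	LL55	laricifolia_laricifolia
LL62_1	LL62	laricifolia_laricifolia
LL62_2	LL62	laricifolia_laricifolia
LL62_3	LL62	laricifolia_laricifolia
LL62_4	LL62	laricifolia_laricifolia
LL65_1	LL65	laricifolia_laricifolia
LL65_2	LL65	laricifolia_laricifolia
LL65_3	LL65	laricifolia_laricifolia
LL65_4	LL65	laricifolia_laricifolia
LL65_5	LL65	laricifolia_laricifolia
LL66_1	LL66	laricifolia_laricifolia
LL66_2	LL66	laricifolia_laricifolia
LL66_3	LL66	laricifolia_laricifolia
LL66_4	LL66	laricifolia_laricifolia
LL67_1	LL67	laricifolia_laricifolia
LL67_2	LL67	laricifolia_laricifolia
LL67_3	LL67	laricifolia_laricifolia
LL67_4	LL67	laricifolia_laricifolia
LL67_5	LL67	laricifolia_laricifolia
LL68_1	LL68	laricifolia_laricifolia
LL68_2	LL68	laricifolia_laricifolia
LL68_3	LL68	laricifolia_laricifolia
LL68_4	LL68	laricifolia_laricifolia
LL68_5	LL68	laricifolia_laricifolia
LL85_1	LL85	laricifolia_laricifolia
LL85_2	LL85	laricifolia_laricifolia
LL85_3	LL85	laricifolia_laricifolia
LL85_4	LL85	laricifolia_laricifolia
LL86_1	LL86	laricifolia_laricifolia
LL86_2	LL86	laricifolia_laricifolia
LL86_3	LL86	laricifolia_laricifolia
LL86_4	LL86	laricifolia_laricifolia
LL88_1	LL88	laricifolia_laricifolia
LL88_2	LL88	laricifolia_laricifolia
LL88_3	LL88	laricifolia_laricifolia
LL88_4	LL88	laricifolia_laricifolia
LL89_1	LL89	laricifolia_laricifolia
LL89_2	LL89	laricifolia_laricifolia
LL89_3	LL89	laricifolia_laricifolia
LL89_4	LL89	laricifolia_laricifolia
LL89_5	LL89	laricifolia_laricifolia
LL92_1	LL92	laricifolia_laricifolia
LL92_2	LL92	laricifolia_laricifolia
LL92_3	LL92	laricifolia_laricifolia
LL92_4	LL92	laricifolia_laricifolia
LL95_1	LL95	laricifolia_laricifolia
LL95_2	LL95	laricifolia_laricifolia
LL96_1	LL96	laricifolia_laricifolia
LL96_2	LL96	laricifolia_laricifolia
LL96_3	LL96	laricifolia_laricifolia
LL96_4	LL96	laricifolia_laricifolia
LL96_5	LL96	laricifolia_laricifolia
LL98_1	LL98	laricifolia_laricifolia
LL98_2	LL98	laricifolia_laricifolia
LL98_3	LL98	laricifolia_laricifolia
LL98_4	LL98	laricifolia_laricifolia
LL98_5	LL98	laricifolia_laricifolia
LL99_1	LL99	laricifolia_laricifolia
LL99_2	LL99	laricifolia_laricifolia
LL99_3	LL99	laricifolia_laricifolia
LL99_4	LL99	laricifolia_laricifolia
LL99_5	LL99	laricifolia_laricifolia
LL218_1	LL218	laricifolia_laricifolia
LL218_2	LL218	laricifolia_laricifolia
LL218_3	LL218	laricifolia_laricifolia
LL218_4	LL218	laricifolia_laricifolia
LL218_5	LL218	laricifolia_laricifolia
LL219_1	LL219	laricifolia_laricifolia
LL219_2	LL219	laricifolia_laricifolia
LL219_3	LL219	laricifolia_laricifolia
LL220_1	LL220	laricifolia_laricifolia
LL220_2	LL220	laricifolia_laricifolia
LL220_3	LL220	laricifolia_laricifolia
LL220_4	LL220	laricifolia_laricifolia
LL220_5	LL220	laricifolia_laricifolia
LL273_1	LL273	laricifolia_laricifolia
LL273_2	LL273	laricifolia_laricifolia
LL273_3	LL273	laricifolia_laricifolia
LL273_4	LL273	laricifolia_laricifolia
LL273_5	LL273	laricifolia_laricifolia
LO50_1	LO50	laricifolia_ophiolitica
LO50_2	LO50	laricifolia_ophiolitica
LO50_3	LO50	laricifolia_ophiolitica
LO50_4	LO50	laricifolia_ophiolitica
LO50_5	LO50	laricifolia_ophiolitica
LO51_1	LO51	laricifolia_ophiolitica
LO51_2	LO51	laricifolia_ophiolitica
LO51_3	LO51	laricifolia_ophiolitica
LO51_4	LO51	laricifolia_ophiolitica
LO51_5	LO51	laricifolia_ophiolitica
LO52_1	LO52	laricifolia_ophiolitica
LO52_2	LO52	laricifolia_ophiolitica
LO52_3	LO52	laricifolia_ophiolitica
LO52_4	LO52	laricifolia_ophiolitica
LO52_5	LO52	laricifolia_ophiolitica
PA_1	PA	parnonia
PA_2	PA	parnonia
PA_3	PA	parnonia
PA_4	PA	parnonia
PA229_1	PA229	parnonia
LA237_1	LA237	rupestris
LA237_2	LA237	rupestris
LA237_3	LA237	rupestris
LA237_4	LA237	rupestris
LA237_5	LA237	rupestris
SE152_1	SE152	sedoides
SE46_1	SE46	sedoides
WE_1	WE	wettsteinii
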