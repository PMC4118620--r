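condition	replicate	time_min	lactate_conc
vehicle	1	30	58.6507411591352
vehicle	1	60	105.656302136428
vehicle	1	90	169.141860013266
vehicle	1	120	210.66962515806
IA_low	1	30	70.2137329337871
IA_low	1	60	146.2784244895
IA_low	1	90	204.441129542344
IA_low	1	120	284.523926626694
IA_high	1	30	25.1531892674014
IA_high	1	60	51.7778363594502
IA_high	1	90	80.9194585285936
IA_high	1	120	107.398471103456
vehicle	2	30	51.4874929766241
vehicle	2	60	113.292883407731
vehicle	2	90	155.914597719952
vehicle	2	120	214.250288524573
IA_low	2	30	75.8823103181736
IA_low	2	60	144.112890577699
IA_low	2	90	215.656871245389
IA_low	2	120	289.55685761994
IA_high	2	30	27.9467494708516
IA_high	2	60	53.4222390932237
IA_high	2	90	83.8889188032246
IA_high	2	120	109.479627429641
vehicle	3	30	53.0317347420729
vehicle	3	60	102.111746726318
vehicle	3	90	159.615361816937
vehicle	3	120	211.413199475126
IA_low	3	30	62.1014542677646
IA_low	3	60	141.545965686359
IA_low	3	90	215.134753943848
IA_low	3	120	294.360583073947
IA_high	3	30	33.2245731026078
IA_high	3	60	58.4338035739342
IA_high	3	90	76.6106326204609
IA_high	3	120	100.55757713449
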