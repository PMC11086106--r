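dataset	metric	loo_mean	loo_std	cal1_mean	cal1_std	cal2_mean	cal2_std
chbmit	ACC	50.70	7.83	56.26	4.40	61.02	5.81
chbmit	SEN	44.02	10.38	52.89	11.66	58.44	10.47
chbmit	SPE	60.95	13.34	63.44	12.65	66.84	13.13
conegliano	ACC	50.08	6.71	58.49	5.70	62.73	4.71
conegliano	SEN	46.06	19.54	69.22	17.07	73.52	16.34
conegliano	SPE	50.21	13.02	65.85	11.44	70.68	14.66
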