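dataset	metric	loo_mean	loo_std	cal1_mean	cal1_std	cal2_mean	cal2_std	f_value
chbmit	ACC	53.55	8.54	65.77	10.26	69.35	9.34	14.30
chbmit	SEN	40.28	17.47	62.75	16.96	69.74	15.51	15.24
chbmit	SPE	54.31	11.70	68.27	8.82	69.90	8.98	36.79
conegliano	ACC	45.72	8.50	63.27	9.34	70.67	8.53	28.00
conegliano	SEN	40.72	12.18	62.62	12.24	75.37	12.60	19.97
conegliano	SPE	52.56	10.34	67.19	12.10	71.28	11.96	16.03
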