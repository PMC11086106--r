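id	gender	n_seizures	rcv_acc	rcv_sen	rcv_spe	loo_acc	loo_sen	loo_spe	cal1_acc	cal1_sen	cal1_spe	cal2_acc	cal2_sen	cal2_spe
chb04	m	3	84.11	66.86	95.98	38.16	27.03	56.24	49.40	45.12	60.56	56.59	53.84	63.24
chb05	f	5	79.94	85.71	62.80	55.71	33.60	50.10	56.92	45.43	68.47	59.72	55.78	69.58
chb06	f	7	82.05	60.11	91.47	59.90	42.33	63.36	67.35	58.95	76.37	69.22	62.30	78.41
chb07	f	3	77.86	97.31	64.71	59.83	50.35	55.05	63.66	59.47	77.37	66.36	61.49	79.46
chb09	f	3	87.74	96.27	65.45	62.47	76.54	29.48	79.28	91.61	50.72	82.11	93.47	51.77
chb10	m	7	64.63	97.17	64.78	58.37	42.37	52.91	64.21	55.52	68.99	65.49	61.47	70.66
chb20	f	6	87.03	84.66	77.74	46.66	28.66	58.15	65.49	61.01	70.71	73.75	80.87	71.14
chb22	f	3	93.99	98.31	69.22	47.33	21.36	69.20	79.84	84.87	72.96	81.55	88.66	74.95
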