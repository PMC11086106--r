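id	gender	n_seizures	rcv_acc	rcv_sen	rcv_spe	loo_acc	loo_sen	loo_spe	cal1_acc	cal1_sen	cal1_spe	cal2_acc	cal2_sen	cal2_spe
p1	m	4	97.12	98.00	96.09	35.40	38.96	31.46	57.58	68.72	50.55	59.36	76.69	51.10
p2	m	5	89.33	93.18	84.70	50.97	43.23	60.44	52.88	49.33	61.93	63.96	83.61	62.46
p3	f	5	88.82	88.82	88.83	50.71	52.97	48.73	68.24	54.87	84.53	70.61	60.68	88.21
p4	f	6	94.84	91.98	97.66	48.45	31.80	64.46	69.35	62.28	74.17	75.13	78.76	74.68
p5	f	4	99.18	99.86	97.93	53.91	50.63	58.98	80.15	82.35	77.02	84.96	93.10	79.54
p6	f	3	98.48	99.10	97.20	29.93	16.35	57.46	66.42	72.71	64.51	77.23	75.14	78.45
p7	f	7	97.46	95.68	99.60	50.47	51.04	49.80	56.11	64.82	51.89	62.41	81.19	61.74
p8	m	10	84.98	82.27	86.61	45.94	40.80	49.12	55.39	45.90	72.93	71.72	53.79	74.05
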