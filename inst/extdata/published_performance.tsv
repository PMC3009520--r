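scheme	window	threshold	Sn	Sp	Acc	MCC	balanced	consistent
binary	15	-1	100	0	50	0	FALSE	TRUE
binary	15	-0.9	100	0	50	0	FALSE	TRUE
binary	15	-0.8	100	0	50	0	FALSE	TRUE
binary	15	-0.7	100	0.04	50.02	0.01	FALSE	TRUE
binary	15	-0.6	99.98	0.2	50.09	0.03	FALSE	TRUE
binary	15	-0.5	99.75	1.21	50.48	0.06	FALSE	TRUE
binary	15	-0.4	99.08	4.43	51.76	0.11	FALSE	TRUE
binary	15	-0.3	96.98	14.26	55.62	0.2	FALSE	TRUE
binary	15	-0.2	90.34	33.7	62.02	0.29	FALSE	TRUE
binary	15	-0.1	78.21	58.19	68.2	0.37	FALSE	TRUE
binary	15	0	62.36	78.27	70.31	0.41	TRUE	TRUE
binary	15	0.1	46.81	90.16	68.48	0.41	FALSE	TRUE
binary	15	0.2	33.11	95.75	64.43	0.37	FALSE	TRUE
binary	15	0.3	23.9	98.04	60.97	0.33	FALSE	TRUE
binary	15	0.4	17.14	99.2	58.17	0.29	FALSE	TRUE
binary	15	0.5	11.83	99.65	55.74	0.24	FALSE	TRUE
binary	15	0.6	8.58	99.84	54.21	0.21	FALSE	TRUE
binary	15	0.7	5.84	99.92	52.88	0.17	FALSE	TRUE
binary	15	0.8	3.96	99.94	51.95	0.14	FALSE	TRUE
binary	15	0.9	2.12	99.98	51.05	0.1	FALSE	TRUE
binary	15	1	1.27	100	50.63	0.08	FALSE	TRUE
binary	17	-1	87.49	42.38	64.94	0.33	FALSE	TRUE
binary	17	-0.9	86.57	44.27	65.42	0.34	FALSE	TRUE
binary	17	-0.8	85.83	46.08	65.95	0.35	FALSE	TRUE
binary	17	-0.7	84.96	47.89	66.43	0.35	FALSE	TRUE
binary	17	-0.6	84	49.66	66.83	0.36	FALSE	TRUE
binary	17	-0.5	82.95	51.63	67.29	0.36	FALSE	TRUE
binary	17	-0.4	81.85	53.48	67.66	0.37	FALSE	TRUE
binary	17	-0.3	80.76	55.19	67.97	0.37	FALSE	TRUE
binary	17	-0.2	79.73	57	68.37	0.38	FALSE	TRUE
binary	17	-0.1	78.49	58.73	68.61	0.38	FALSE	TRUE
binary	17	0	77	60.57	68.79	0.38	FALSE	TRUE
binary	17	0.1	75.67	62.4	69.04	0.38	FALSE	TRUE
binary	17	0.2	74.57	63.89	69.23	0.39	FALSE	TRUE
binary	17	0.3	73.52	65.42	69.47	0.39	FALSE	TRUE
binary	17	0.4	72.11	67.09	69.6	0.39	FALSE	TRUE
binary	17	0.5	70.53	68.73	69.65	0.39	TRUE	FALSE
binary	17	0.6	68.8	70.23	69.51	0.39	FALSE	TRUE
binary	17	0.7	67.11	71.83	69.47	0.39	FALSE	TRUE
binary	17	0.8	65.34	73.34	69.34	0.39	FALSE	TRUE
binary	17	0.9	63.77	74.45	69.26	0.39	FALSE	FALSE
binary	17	1	62.08	76.2	69.14	0.39	FALSE	TRUE
binary	19	-1	99.98	0.06	50.02	0.01	FALSE	TRUE
binary	19	-0.9	99.96	0.32	50.14	0.03	FALSE	TRUE
binary	19	-0.8	99.92	1.11	50.51	0.07	FALSE	TRUE
binary	19	-0.7	99.68	2.45	51.07	0.09	FALSE	TRUE
binary	19	-0.6	99.08	5.37	52.22	0.13	FALSE	TRUE
binary	19	-0.5	97.75	11.68	54.71	0.19	FALSE	TRUE
binary	19	-0.4	95.74	20.06	57.9	0.24	FALSE	TRUE
binary	19	-0.3	91.64	32.39	62.01	0.3	FALSE	TRUE
binary	19	-0.2	85.52	47.37	66.45	0.36	FALSE	TRUE
binary	19	-0.1	76.76	61.36	69.06	0.39	FALSE	TRUE
binary	19	0	66.26	74.71	70.49	0.41	TRUE	TRUE
binary	19	0.1	55.47	83.9	69.68	0.41	FALSE	TRUE
binary	19	0.2	45.05	90.77	67.91	0.4	FALSE	TRUE
binary	19	0.3	34.78	94.93	64.86	0.37	FALSE	TRUE
binary	19	0.4	26.46	97.15	61.8	0.33	FALSE	TRUE
binary	19	0.5	19.78	98.39	59.09	0.29	FALSE	TRUE
binary	19	0.6	14.21	99.34	56.78	0.26	FALSE	TRUE
binary	19	0.7	9.93	99.74	54.84	0.22	FALSE	TRUE
binary	19	0.8	6.41	99.86	53.14	0.18	FALSE	TRUE
binary	19	0.9	4.06	99.92	51.99	0.14	FALSE	TRUE
binary	19	1	2.43	99.94	51.19	0.11	FALSE	TRUE
pssm	15	-1	98.76	12.48	55.62	0.22	FALSE	TRUE
pssm	15	-0.9	98.38	15.41	57.09	0.25	FALSE	FALSE
pssm	15	-0.8	97.71	20.59	59.15	0.29	FALSE	TRUE
pssm	15	-0.7	96.86	25.68	61.27	0.32	FALSE	TRUE
pssm	15	-0.6	95.82	31.46	63.64	0.36	FALSE	TRUE
pssm	15	-0.5	94.51	38.63	66.57	0.4	FALSE	TRUE
pssm	15	-0.4	93.03	45.54	69.28	0.44	FALSE	TRUE
pssm	15	-0.3	91.2	53.32	72.76	0.48	FALSE	FALSE
pssm	15	-0.2	88.83	62.53	75.68	0.53	FALSE	TRUE
pssm	15	-0.1	85.47	70.86	78.16	0.57	FALSE	TRUE
pssm	15	0	80.85	79.73	80.29	0.61	TRUE	TRUE
pssm	15	0.1	75.62	87.72	81.67	0.64	FALSE	TRUE
pssm	15	0.2	68.59	92.6	80.59	0.63	FALSE	TRUE
pssm	15	0.3	63.42	94.75	79.08	0.61	FALSE	TRUE
pssm	15	0.4	57.6	96.17	76.88	0.58	FALSE	TRUE
pssm	15	0.5	51.38	97.22	74.3	0.55	FALSE	TRUE
pssm	15	0.6	44.2	97.93	71.07	0.5	FALSE	TRUE
pssm	15	0.7	36.42	98.52	67.47	0.45	FALSE	TRUE
pssm	15	0.8	28.11	98.87	63.49	0.38	FALSE	TRUE
pssm	15	0.9	20.29	99.03	59.66	0.31	FALSE	TRUE
pssm	15	1	12.99	99.37	56.18	0.25	FALSE	TRUE
pssm	17	-1	98.41	21.14	59.78	0.31	FALSE	TRUE
pssm	17	-0.9	97.98	25.91	61.95	0.34	FALSE	TRUE
pssm	17	-0.8	97.37	30.92	64.15	0.38	FALSE	TRUE
pssm	17	-0.7	96.25	37.26	66.75	0.42	FALSE	TRUE
pssm	17	-0.6	95.27	43.43	69.35	0.45	FALSE	TRUE
pssm	17	-0.5	94.26	49.72	71.99	0.49	FALSE	TRUE
pssm	17	-0.4	92.87	56.94	74.9	0.53	FALSE	TRUE
pssm	17	-0.3	91.36	63.94	77.65	0.58	FALSE	TRUE
pssm	17	-0.2	89.35	70.79	80.07	0.61	FALSE	TRUE
pssm	17	-0.1	86.7	77.08	81.89	0.64	FALSE	TRUE
pssm	17	0	83.36	82.36	82.86	0.66	TRUE	TRUE
pssm	17	0.1	79.2	87.39	83.3	0.67	FALSE	TRUE
pssm	17	0.2	74.84	91.83	83.34	0.68	FALSE	TRUE
pssm	17	0.3	69.61	94.6	82.1	0.66	FALSE	TRUE
pssm	17	0.4	64.86	96.05	80.45	0.64	FALSE	TRUE
pssm	17	0.5	60.07	97.29	78.68	0.62	FALSE	TRUE
pssm	17	0.6	54.55	98.09	76.32	0.58	FALSE	TRUE
pssm	17	0.7	47.38	98.66	73.02	0.54	FALSE	TRUE
pssm	17	0.8	38.4	99.06	68.73	0.47	FALSE	TRUE
pssm	17	0.9	28.7	99.35	64.03	0.4	FALSE	TRUE
pssm	17	1	19.14	99.57	59.76	0.32	FALSE	FALSE
pssm	19	-1	98.67	13.31	55.99	0.23	FALSE	TRUE
pssm	19	-0.9	98.12	16.81	57.46	0.26	FALSE	TRUE
pssm	19	-0.8	97.6	21.38	59.49	0.29	FALSE	TRUE
pssm	19	-0.7	96.78	26.03	61.41	0.32	FALSE	TRUE
pssm	19	-0.6	95.78	32.19	63.99	0.36	FALSE	TRUE
pssm	19	-0.5	94.51	38.81	66.66	0.4	FALSE	TRUE
pssm	19	-0.4	93	46.04	69.52	0.44	FALSE	TRUE
pssm	19	-0.3	91.34	54.31	72.82	0.49	FALSE	TRUE
pssm	19	-0.2	88.98	62.32	75.65	0.53	FALSE	TRUE
pssm	19	-0.1	85.64	70.92	78.28	0.57	FALSE	TRUE
pssm	19	0	81.86	78.93	80.39	0.61	TRUE	TRUE
pssm	19	0.1	76.12	86.05	81.09	0.62	FALSE	TRUE
pssm	19	0.2	69.28	91.42	80.35	0.62	FALSE	TRUE
pssm	19	0.3	63.44	93.96	78.7	0.6	FALSE	TRUE
pssm	19	0.4	58.06	95.66	76.86	0.58	FALSE	TRUE
pssm	19	0.5	51.18	96.85	74.01	0.54	FALSE	TRUE
pssm	19	0.6	44.01	97.85	70.93	0.5	FALSE	TRUE
pssm	19	0.7	35.65	98.44	67.05	0.44	FALSE	TRUE
pssm	19	0.8	27.5	98.77	63.14	0.37	FALSE	TRUE
pssm	19	0.9	19.19	99.08	59.13	0.3	FALSE	TRUE
pssm	19	1	11.33	99.55	55.44	0.23	FALSE	TRUE
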