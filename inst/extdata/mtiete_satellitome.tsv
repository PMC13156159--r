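name	RUL	AT_percent	abundance	divergence
MtiSat01-650	650	40.1	0.004173716	2.75
MtiSat02-206	206	46.1	0.002758681	2.83
MtiSat03-24	24	66.6	0.001828581	5.31
MtiSat04-30	30	53.3	0.001756834	9.95
MtiSat05-42	42	54.76	0.001689457	13.36
MtiSat06-177	177	66.1	0.001369735	4.11
MtiSat07-2108	2108	61.2	0.001247475	9.56
MtiSat08-51	51	62.7	0.001168871	3.01
MtiSat09-54	54	53.7	0.001013885	12.16
MtiSat10-72	72	65.2	0.000960619	7.76
MtiSat11-74	74	58.1	0.000897454	11.77
MtiSat12-1119	1119	45.1	0.000876148	26.7
MtiSat13-66	66	62.1	0.000867789	7.2
MtiSat14-68	68	63.2	0.000831528	6.48
MtiSat15-101	101	59.4	0.000781993	5.36
MtiSat16-2265	2265	52	0.000586849	14.46
MtiSat17-1057	1057	48.5	0.000585767	1.38
MtiSat18-28	28	46.4	0.000479841	2.04
MtiSat19-221	221	60.1	0.00043594	8.73
MtiSat20-62	62	66.1	0.000414246	14.22
MtiSat21-946	946	62.4	0.000387092	2.55
MtiSat22-142	142	51.4	0.000373817	7.7
MtiSat23-1440	1440	59	0.000350487	3.51
MtiSat24-60	60	40	0.000345526	9.43
MtiSat25-1258	1258	56.5	0.000315714	10.48
MtiSat26-24	24	62.5	0.000230351	10.54
MtiSat27-34	34	55.8	0.000209212	8.46
MtiSat28-165	165	55.1	0.000160133	4.07
MtiSat29-1738	1738	53.5	0.000131676	1.74
MtiSat30-40	40	60	0.000119471	8.32
MtiSat31-1112	1112	54.1	0.000106657	4.9
MtiSat32-903	903	60.1	8.38e-05	6.75
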