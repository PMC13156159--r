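Mti	Cma	Pme
MtiSat04-30	CmaSat18-30	PmeSat19-30
MtiSat05-42	CmaSat09-42	PmeSat07-42
MtiSat06-177	CmaSat03-177	PmeSat08-177
MtiSat07-2108	-	PmeSat09-696
MtiSat08-51	CmaSat29-34	-
MtiSat09-54	CmaSat31-54	PmeSat21-54
MtiSat10-72	CmaSat20-72	PmeSat12-72
MtiSat13-66	CmaSat33-66	PmeSat18-67
MtiSat14-68	CmaSat22-68	PmeSat17-65
MtiSat15-101	CmaSat34-101	PmeSat27-102
MtiSat18-28	CmaSat21-28	PmeSat22-28
MtiSat27-34	-	PmeSat07-42
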