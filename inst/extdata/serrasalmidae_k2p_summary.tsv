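species_pair	n	k2p_mean	k2p_sd	t_myr	ctr_myr_mean	ctr_myr_sd
Cma|Mti	10	1.59	1.11	40	0.0199	0.0139
Cma|Pme	9	1.40	0.67	34.9	0.0201	0.0096
Mti|Pme	11	1.28	0.74	40	0.0160	0.0093
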