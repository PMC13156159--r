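family_pair	k2p	t_myr	note
MtiSat07-2108/PmeSat09-696	2.53	40	highest pairwise K2P in the three-species comparison
MtiSat14-68/CmaSat22-68/PmeSat17-65	0.50	NA	lowest K2P (mean over its pairwise comparisons)
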