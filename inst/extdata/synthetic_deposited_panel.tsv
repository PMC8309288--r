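# synthetic stand-in for the eight deposited allele sequences
# generated by fleshmark simulate_panel(seed = 104)
accession_id	line_name	subtype	group	flesh_phenotype	allele_ids
HKR-397	HKR-397	GsRf	Rf	red	GsRf_TT8_1,GsRf_TT8_2
HKR-275	HKR-275	RsRf	Rf	red	RsRf_TT8_1,RsRf_TT8_2
HKR-519	HKR-519	WsWf	Wf	white	WsWf_TT8_1,WsWf_TT8_2
HKR-513	HKR-513	RsWf	Wf	white	RsWf_TT8_1,RsWf_TT8_2
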