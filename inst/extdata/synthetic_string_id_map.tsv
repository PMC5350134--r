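9606.ENSP0000001	ALDH1A2
9606.ENSP0000002	RDH10
9606.ENSP0000003	CYP26A1
9606.ENSP0000004	CYP26C1
9606.ENSP0000005	DHRS3
9606.ENSP0000006	ADH1B
9606.ENSP0000007	ADH5
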