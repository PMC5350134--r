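Official Symbol Interactor A	Official Symbol Interactor B	Experimental System
ALDH1A2	RDH10	Two-hybrid
CYP26A1	ALDH1A2	Affinity Capture-MS
ALDH1A2	ADH5	Two-hybrid
ALDH1A2	DHRS3	Affinity Capture-Western
GENEX	GENEY	Two-hybrid
ALDH1A2	ALDH1A2	Two-hybrid
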