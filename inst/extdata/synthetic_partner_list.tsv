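symbol	description	synonyms
RDH10	retinol dehydrogenase 10	SDR16C4
SDR16C4	short chain dehydrogenase/reductase family 16C member 4
CYP26A1	cytochrome P450 family 26 subfamily A member 1	CP26,CYP26
CYP26C1	cytochrome P450 family 26 subfamily C member 1	FFDD4
ADH5	alcohol dehydrogenase 5 (class III)	ADHX,FDH
DHRS3	dehydrogenase/reductase 3	RDH17,SDR16C1
ADH1B	alcohol dehydrogenase 1B (class I)	ADH2
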