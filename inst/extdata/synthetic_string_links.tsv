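protein1 protein2 neighborhood fusion cooccurence coexpression experiments database textmining combined_score
9606.ENSP0000001 9606.ENSP0000002 0 0 0 0 0 0 700 720
9606.ENSP0000001 9606.ENSP0000003 0 0 0 600 0 800 300 850
9606.ENSP0000001 9606.ENSP0000004 0 0 0 0 0 0 900 900
9606.ENSP0000001 9606.ENSP0000005 0 0 120 0 0 0 450 480
9606.ENSP0000006 9606.ENSP0000002 0 0 0 500 0 0 600 650
9606.ENSP0000001 9606.ENSP0000007 0 0 0 150 0 0 320 340
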