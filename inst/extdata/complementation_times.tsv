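enzyme	delta_hisA_h	delta_trpF_h	delta_hisA_trpF_h
scPriA	22	22	23
tmHisA	16	114	144
ddHisA	16	153	181
pcHisA	15	70	63
CA-Act-HisA	48	23	47
CA-Prot-HisA	16	33	28
CA-Bact-HisA	16	45	39
tmTrpF	NA	24	NA
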