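enzyme	reaction	kcat_s	KM_uM	eff_printed_Ms
scPriA	HisA	0.9	28	NA
mtPriA	HisA	0.23	19	NA
tmHisA	HisA	1.0	5.6	NA
ddHisA	HisA	1.3	2.8	NA
pcHisA	HisA	0.4	1.8	NA
seHisA	HisA	7.8	17.0	NA
CA-Act-HisA	HisA	NA	NA	300
CA-Prot-HisA	HisA	0.05	0.3	NA
CA-Bact-HisA	HisA	0.05	0.5	NA
scPriA	TrpF	12	4	NA
mtPriA	TrpF	3.6	21	NA
tmHisA	TrpF	0.0067	60	NA
ddHisA	TrpF	0.0023	161	NA
pcHisA	TrpF	0.001	303	NA
CA-Act-HisA	TrpF	0.01	3	NA
CA-Prot-HisA	TrpF	0.00053	2.7	NA
CA-Bact-HisA	TrpF	0.00023	3.2	NA
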