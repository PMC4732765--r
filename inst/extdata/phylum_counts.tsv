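phylum	n_species
Euryarchaeota	5
Crenarchaeota	20
Bacteroidetes	8
Firmicutes	11
Spirochaetes	5
Alphaproteobacteria	21
Betaproteobacteria	5
Gammaproteobacteria	1
Deltaproteobacteria	5
Actinobacteria	22
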