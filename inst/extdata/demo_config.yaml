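# Fully synthetic end-to-end demo at desk scale.
seed: 42
n_species: 10
neighbor_fraction: 0.8
divergence: 0.4
indel_rate: 0.02
gap_threshold: 0.5
identity_collapse: 95
evalue_cutoff: 1.0e-54
chains: 4
samples: 300
burnin_frac: 0.1
model: JTT
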