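# Shared configuration for the numbered analysis scripts.  Every stage
# reads and writes under out_dir; each script enables one stage, so the
# whole analysis can be reproduced by running 01..06 in order.
out_dir: results/analysis
seed: 20260101
n_families: 3
lambda: 0.1
mu: 0.05
n0: 1
n_codons: 200
regime: one_ratio
omega: 0.2
branch_scale: 0.06
artifacts: true
n_alleles: 2
n_fragments: 1
min_len_nt: 400
allele_identity: 0.95
column_threshold: 12
n_bootstrap: 200
recent_max_species: 2
ds_max: 2
branch_mode: scale
fit_switching: false
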