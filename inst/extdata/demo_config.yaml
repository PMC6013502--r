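# demo pipeline configuration: one locus, two tissues, one planted
# shared causal variant driving expression (h2 = 0.3) and disease
# risk (F = 0.01), plus a rare-variant burden panel with damaging
# case enrichment
seed: 101
n_samples: 300
n_variants: 150
block_length: 15
block_r2: 0.8
eqtl_h2: 0.3
n_probes_null: 2
tissues: [CD4, CD8]
theta_threshold: 0.6
informative_threshold: 1.3
k: 30.0
T: 0.3
weight_exponent: 1
cis_half_window: 1000000
maf_common: 0.05
maf_rare: 0.005
n_perm_eqtl: 200
n_perm_burden: 300
n_perm_outer: 100
dap_F: 0.01
dap_n1: 2000
dap_n2: 2000
rare_n_genes: 4
rare_rr_damaging: 3
n_rare_cases: 1500
n_rare_controls: 1500
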