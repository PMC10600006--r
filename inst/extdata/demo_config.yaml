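# Demo pipeline configuration: a small admixed cohort on two chromosomes.
seed: 10
stages: [simulate, roh, ibd, ne, burden, traits]
sim:
  n_individuals: 25
  n_variants: 400
params:
  max_ibd_pairs: 60
  ne_G: 10
  min_roh_snps: 5
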