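version: 1
seed: 1
simulation:
  genome_size: 5000000.0
  n_chroms: 2
  tree_newick: (((L1:1,L2:1):0.6,(L3:1,L4:1):0.6):0.6,L5:2.2);
  rate_per_branch: 45.0
  stem_length: 0.3
  type_weights:
    insertion: 0.34
    deletion: 0.34
    tandem_expansion: 0.07
    tandem_contraction: 0.07
    repeat_expansion: 0.07
    repeat_contraction: 0.07
    inversion: 0.04
  size_range:
  - 50
  - 10000
  inv_size_range:
  - 10000
  - 30000
  min_spacing: 5000
  repeat_config:
    tandem_unit_range:
    - 15
    - 30
    tandem_copy_range:
    - 6
    - 15
    tandem_array_count: 150
    dispersed_repeat_length: 500
    dispersed_repeat_count: 20
  annotation:
    n_genes: 300
    exons_per_gene:
    - 2
    - 6
    exon_length:
    - 100
    - 400
  label_map:
    motif: CACGAG
    miss_prob: 0.1
    false_per_100kb: 1.0
    sizing_cv: 0.005
thresholds:
  min_size: 50
  max_size: 50000
  min_match: 500
  min_cluster_match: 100
  map_min_size: 1000
  tol: 3
  k: 21
  max_gap: 50000
  inversion_min_size: 10000
bootstrap:
  B: 1000
  scales:
  - 0.5
  - 0.6
  - 0.7
  - 0.8
  - 0.9
  - 1.0
  - 1.1
  - 1.2
  - 1.3
  - 1.4
rate:
  divergence_my: 2.2
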