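# Example hexniche pipeline configuration: simulate a small two-slide
# dataset and run the full analysis. See ?pipelineConfig and
# ?syntheticConfig for every field.
simulate:
  seed: 1
  n_rows: 24
  n_cols: 24
  n_genes: 1000
  n_response_genes_tumor: 60
  n_response_genes_benign: 20
  immune_spot_fraction: 0.046
  depth_deep_mean: 20000
niche:
  score_threshold: 0.9
  min_marker_coverage: 0.5
de:
  min_pct: 0.1
  lfc_min: 0.25
  alpha: 0.05
depth:
  rate: 0.02857143
composition:
  nPerCell: 20
hvg_n: 1000
n_perm: 999
output_dir: hexniche_example_run
seed: 1
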