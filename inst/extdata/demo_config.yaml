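# Demo run: simulate a wild-type-like footprinting sample on the toy
# genome, aggregate, smooth and call spread boundaries at each anchor.
seed: 7
simulate:
  coverage: 30
  mean_read_length: 8000
  dispersion: 0.25
  tpr: 0.9
  fpr: 0.01
  model:
    lambda: 800
    boundary_attenuation: 0.1
    background: 0.02
    rate: 0.8
    peak: 0.9
    promoter_peak: 0.6
    linker_accessibility: 1.0
    core_accessibility: 0.2
analysis:
  threshold: 0.8
  min_coverage: 10
  enp_target: 100
  merge_strands: true
  background_k: 2
  run_length: 300
out_dir: results/demo
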