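# Example experiment configuration for the voicerisk CLI:
#   Rscript inst/cli/voicerisk.R run --config experiment-example.yaml --out results/
synth:
  "n": 1000
  seed: 11
  target_balance: 0.5
rule:
  hnr_min: 20
  jitter_max: 0.005
training:
  epochs: 50
  patience: 10
test_frac: 0.2
seed: 11
baselines: [dnn, knn]
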