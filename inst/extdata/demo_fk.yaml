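# Demo experiment: randomly paced Fenton-Karma dataset forecast by the
# baseline and clustered echo state networks at 100 neurons.
dataset:
  model: fk
  seed: 1
  n_beats: 100
  mean_cl: 320
  sd_cl: 50
  amplitude: 0.4
  duration: 2
  dt: 0.1
  dv_threshold: 0.02
  dt_max: 20
  n_warmup_beats: 10
  n_train_beats: 71
methods:
  - kind: esn
    n_neurons: 100
    seed: 1
  - kind: clustered_esn
    n_neurons: 100
    n_clusters: 4
    seed: 1
evaluation:
  threshold: 0.3
  n_seeds: 10
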