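# Reduced demonstration study: 2 training + 2 testing subjects, one short
# phase per session and a down-sized network, so the full pipeline runs in
# well under a minute. The full-scale study settings are the package
# defaults (see ?sim_config, ?sae_hyperparams and the analysis/ scripts).
seed: 2024
sim:
  n_phases: 1
  targets_per_phase: 10
  noise_model:
    pink_sd: 2
    alpha_amplitude: 2
    white_sd: 1
profiles_train:
  - subject_id: demo-train-1
    p300_amplitude: 7
    p300_latency: 380
  - subject_id: demo-train-2
    p300_amplitude: 6
    p300_latency: 420
profiles_test:
  - subject_id: demo-test-1
    p300_amplitude: 6.5
    p300_latency: 400
  - subject_id: demo-test-2
    p300_amplitude: 5
    p300_latency: 430
sae_hyper:
  layer_sizes: [50, 20]
  max_pretrain_epochs: 60
  softmax_iterations: 100
  finetune_iterations: 100
mlp_iterations: 200
models: [sae, mlp, lda]
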