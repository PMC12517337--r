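# Example experiment configuration: a small skewed two-silo collaboration
# trained with FedProx at a 50% client rate. Load with
# read_experiment_config(); all randomness flows from the seeds below.
cohort:
  variant_type: coding_snv
  class_sep: 1.5
  seed: 11
  test1_n: 200
  test2_n: 100
  silos:
    - {silo_id: large_center, n_variants: 600}
    - {silo_id: small_center, n_variants: 120}
model: {type: mlp, input_dim: 60, n_hidden: 6}
local: {learning_rate: 0.05, optimizer: sgd, batch_size: 32, epochs: 10}
aggregator: {algorithm: fedprox, proximal_mu: 0.01, client_rate: 0.5, n_rounds: 20}
seeds: [1, 2, 3]
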