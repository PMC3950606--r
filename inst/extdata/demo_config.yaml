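# One-command synthetic-study demo: simulate -> segment -> metrics ->
# model tables -> mixed-model fits. Deterministic under `seed`.
simulate:
  n_days: 120
seed: 1
ac: grid
out_dir: mguard_demo
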