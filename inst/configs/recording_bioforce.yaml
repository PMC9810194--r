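# Effective-connectivity fitting: a connectome-constrained network with one
# model neuron per recorded trace is trained (per-neuron RLS, self-loops
# excluded) to reproduce a synthetic teacher-network recording, with early
# stopping on validation MAE. Small preset (N=50, T=500); the full
# recording scale is N=365, T=2500 at dt=0.25 s.
seed: 1
task:
  generator: synthetic_recording
  params:
    n_neurons: 50
    n_steps: 500
    dt: 0.25
layer:
  kind: constrained_esn
  n_neurons: 50
  params:
    sparsity: 0.2
    gain: 0.8
    tau: 1.0
    dt: 0.25
    w_out_init: zeros
trainer:
  kind: bio_force
  alpha: 1
  epochs: 30
  early_stopping:
    patience: 5
    min_delta: 0
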