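# Desk-scale spiking FORCE: a theta-neuron network learns the Lorenz
# attractor as an autonomous target. One continuous session: 1 s warmup
# (2000 steps at dt = 5e-4 s), RLS decoder updates every 2 steps (1 ms),
# then a frozen validation pass.
seed: 1
task:
  generator: lorenz
  params:
    duration_s: 5
    dt: 5.0e-4
layer:
  kind: theta
  n_neurons: 300
  params:
    dt: 5.0e-4
    sparsity: 0.5
    gain: 20
    feedback_scale: 10
trainer:
  kind: spiking
  alpha: 1
  epochs: 2
  update_interval: 2
  warmup_steps: 2000
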