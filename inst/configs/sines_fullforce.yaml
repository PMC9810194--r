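# full-FORCE training (recurrent + readout, shared P) of the same
# 400-neuron no-feedback reservoir on the sum-of-sines task; the zero hint
# channel is supplied to both the task and the target-generating network.
seed: 1
task:
  generator: sum_of_sines
layer:
  kind: nofeedback_esn
  n_neurons: 400
  params:
    gain: 1.5
    tau: 10
    dt: 1
trainer:
  kind: full_force
  alpha: 1
  epochs: 10
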