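# Classic FORCE readout training of a 400-neuron no-feedback reservoir on
# the autonomous sum-of-sines task (input on for the first 20 of 801 steps,
# zero hint channel appended as an extra input dimension).
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
  kind: force
  alpha: 1
  epochs: 10
output:
  downsample: 1
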