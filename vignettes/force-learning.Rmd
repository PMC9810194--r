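---
title: "FORCE learning for chaotic recurrent networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{FORCE learning for chaotic recurrent networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forcenet)
```

## The problem

A recurrent neural network in the chaotic regime has rich spontaneous
dynamics, and a surprisingly small intervention — training a linear readout
whose output is fed back into the network — suffices to sculpt those
dynamics into arbitrary temporal patterns. First-Order Reduced and
Controlled Error (FORCE) learning achieves this with a recursive
least-squares (RLS) rule that keeps the output error small at *every*
training step, so the feedback the network receives during training is
always close to the target it is supposed to produce. This sidesteps the
credit-assignment-through-chaos problem that plagues gradient methods on
long-horizon autonomous tasks, and it makes the approach attractive in
computational neuroscience, where one often wants to constrain a network
model with recorded neural activity and ask what effective connectivity
could have produced it.

`forcenet` separates **layers** (the forward dynamics: rate reservoirs
with/without feedback, connectome-constrained reservoirs, and LIF /
Izhikevich / theta spiking networks) from **trainers** (classic FORCE,
full-FORCE, spiking-decoder FORCE, and per-neuron constrained fitting).
Any compatible layer/trainer pair can be combined, so the package doubles
as a general reservoir-computing toolkit.

## Rate networks

The discrete forward pass is the Euler step of the usual leaky-integrator
dynamics,

$$
x(t) = x(t-\Delta t) + \frac{\Delta t}{\tau}\Big(-x(t-\Delta t)
 + w_{in}^\top f_{in}(t) + w_R^\top r(t-\Delta t)
 + w_F^\top z(t-\Delta t)\Big),
$$

with rates $r = H(x)$ (tanh by default, pluggable by name) and linear
readout $z = w_{out}^\top r$. Feedback always uses the *previous* step's
readout; there is no same-step feedback and no adaptive stepping. Recurrent
weights are drawn $\mathcal N(0,\, g^2/(pN))$ on a Bernoulli$(p)$ support:
$g > 1$ puts the autonomous network in the chaotic regime, and $g = 1.5$
(the conventional choice) is the default. In the memoryless limit
$\tau = \Delta t$ the decay cancels exactly, which the tests exploit as an
algebraic identity. Halving $\Delta t$ halves the distance to a fine-step
reference trajectory — the expected first-order behaviour of the Euler
scheme, and what the step-size test asserts.

The connectome-constrained variant reuses the same dynamics under a boolean
mask with a false diagonal (no self-loops); masked entries are zero at
initialization and are never touched by any operation. Per-neuron time
constants are not implemented: the constrained variant differs from the
unconstrained one only through its mask.

## The RLS machinery

All trainers share one primitive, the rank-one inverse update
$P' = P - \frac{(P r)(P r)^\top}{1 + r^\top P r}$ with
$P(0) = \alpha^{-1} I$, so that $P(t) = (\alpha I + \sum_s r_s
r_s^\top)^{-1}$ at all times. $\alpha$ (default 1) is simultaneously the
ridge regularizer and an inverse learning rate. $P$ is re-symmetrized
after every update; the tests require agreement with the directly inverted
oracle to $10^{-8}$ relative Frobenius error and symmetry to $10^{-10}$.

Within a step the ordering is fixed: forward pass, rates, readout, $P$
update, a-priori error $e_- = z - f_{out}$ (computed with the pre-update
weights), then the pseudogradient update
$w_{out} \leftarrow w_{out} - (P r)\, e_-^\top$. With zero initial readout
weights and rates that do not depend on the readout, one pass of this
recursion *equals* the closed-form ridge solution
$(\alpha I + \sum r r^\top)^{-1} \sum r\, f$ — not approximately but to
machine precision — which is the package's strongest correctness oracle.
Multi-dimensional outputs share a single $P$ (the standard practice);
recurrent-weight training is defined for scalar outputs only, each neuron
$i$ carrying its own matrix $A^i$ over its presynaptic set $B(i)$. Under
full connectivity every $A^i$ equals the shared $P$ bit-for-bit because
both code paths call the same rank-one kernel.

## Trainers

**Classic FORCE** (`force_fit`) trains the readout (optionally the
recurrent matrix) in closed loop. Epoch semantics follow the
sequence-training convention of the high-level APIs this design mirrors:
the network state resets to the stored initial state at the start of every
epoch and of every validation pass, while $P$ (and the $A^i$) persist
across epochs. Validation re-runs the training input/target without
updates at each epoch's end; with no feedback path the reservoir
trajectory is identical across epochs, which makes the per-epoch MAE
directly comparable. Updates fire every $k$-th step after a per-epoch
warmup, giving exactly $\lfloor (T - \text{warmup})/k \rfloor$ updates per
epoch.

**full-FORCE** (`full_force_fit`) removes the feedback loop entirely: a
separate target-generating network with fixed random weights is driven by
the target (and any hint channels), and the task network's recurrent
weights are trained so its internal recurrent currents match the target
network's currents plus the target-drive term, while the readout is
trained on the output error. Both trainable parts share one $P$ over the
task network's rates, so the per-step cost is $O(N^2)$ versus $O(N^3)$
for classic recurrent FORCE. Hint inputs are concatenated input
dimensions; the sum-of-sines generator ships an all-zero hint channel for
exactly this use. The amplitude of the fixed target-injection weights is
a genuine design freedom: validation error is flat for moderate injection
and degrades clearly once the drive saturates the generator's currents,
so the default (`target_drive_scale = 0.5`) sits in the flat region.

**Spiking FORCE** (`spiking_fit`) decodes the double-exponentially
filtered spike trains: $P$ is maintained over `syn_r` and only the
decoders $\phi$ are learned, with feedback $Q\,\eta^\top z$ closing the
loop throughout. The spiking trainer deliberately does *not* reset state
between epochs: it emulates one continuous session — settle (warmup),
train with updates every $k$ steps, then freeze — and validation continues
from a snapshot of the live state. A fixed-phase reset would make
autonomous targets unlearnable in wall-clock-sized experiments, since the
network would need to re-align its phase from scratch each epoch.

**Constrained fitting** (`bio_force_fit`) places one model neuron per
recorded trace and trains each neuron's incoming weights (restricted to
its presynaptic set, never the diagonal) so its activity matches its
trace. By default the fitting is teacher-forced: the recurrent drive uses
the recorded rates, the currents are propagated recursively, and the RLS
features are the *leak-filtered* presynaptic data rates
$f(t) = (1-\Delta t/\tau) f(t-\Delta t) + (\Delta t/\tau)\, y(t-\Delta t)$
— exactly the sensitivity of the current to the weights, so the recursion
solves the induced least-squares problem rather than an approximation to
it. Closed-loop training (`teacher_forcing = FALSE`) is available but
converges to visibly worse effective weights, because its features drift
with the partially trained network. Errors are measured on rates by
default (`match = "currents"` switches to the inverse-activation scale);
traces are clipped into the activation range for the inverse, and only
grossly out-of-range recordings are rescaled, since rescaling distorts
the very dynamics being fitted. Validation is a closed-loop pass from the
trace-matched initial state; early stopping watches it and the best-epoch
weights are restored.

## Spiking layers

Voltage equations use the standard conventions: LIF
$\tau_m \dot v = -(v - v_{rest}) + R I$ with threshold/reset/refractory
(defaults $-40$ / $-65$ mV, 2 ms); the theta model
$\dot\theta = (1-\cos\theta) + (1+\cos\theta) I$, which fires with period
$\pi/\sqrt I$ under constant drive — the closed form the tests check to
1% — with refractoriness implemented as a phase hold; and the canonical
Izhikevich form (per-millisecond equations, `dt` given in seconds).
Spikes are assigned to the step of threshold crossing with no
interpolation; the $O(\Delta t)$ bias this introduces is absorbed by the
1% tolerances. The synapse is two coupled first-order filters
($\tau_d > \tau_r$, defaults 20 ms / 2 ms) advanced by *exact*
exponential integration, not Euler, so a single spike reproduces the
unit-area impulse response
$(e^{-t/\tau_d} - e^{-t/\tau_r})/(\tau_d - \tau_r)$ to machine precision;
each spike increments the auxiliary state by $1/(\tau_r \tau_d)$.
Default biases (LIF 30, theta 500, Izhikevich 5) put few-hundred-neuron
networks in an asynchronous spontaneously spiking regime.

## Synthetic tasks

All experiment inputs are generated internally, so every trainer is
testable without downloads.

* **Sum of sines** (801 steps, input constant for the first 20 then
  silent, zero hint channel): the component frequencies are harmonics
  1, 2, 3, 5 of one cycle per 800 steps with $1/k$ amplitude weighting,
  normalized to unit peak. The harmonic mix is a calibration choice — the
  task family fixes the input gating and length, not the exact waveform.
* **Lorenz** ($\sigma = 10, \rho = 28, \beta = 8/3$, RK4 fixed step via
  the `deSolve` integrator, trajectory divided by 10 so tanh-range
  readouts can match it).
* **Delayed response**: a 0.5 s boxcar at a seeded uniform onset, target
  an identical boxcar 50 ms after input offset; defaults 5 s at
  $10^{-4}$ s, i.e. 5000 high samples, 500-sample lag, 50 000 samples.
* **Synthetic recording**: a connectome-constrained teacher with known
  weights, simulated past a burn-in and observed with additive Gaussian
  noise (default sd 0.01). The teacher is a subcritical random matrix
  (gain 0.8) plus a planted rank-2 amplifying rotation (gain 1.8,
  0.8 rad per time constant, projected onto the connectome support) that
  saturates into a stable network-wide limit cycle. This emulates the
  dominant low-dimensional oscillatory structure of real population
  recordings — smooth traces, lag-1 autocorrelation above 0.5 for
  essentially all neurons, strong cross-correlations — while remaining
  predictable enough that recovered effective weights can be judged on a
  held-out segment. What it does **not** emulate: strongly chaotic
  background activity (a strongly chaotic teacher makes held-out
  free-running prediction impossible *in principle* for any fitting
  method, since even the true weights cannot beat the Lyapunov horizon),
  calcium-indicator dynamics, or non-Gaussian imaging noise. Passing the
  recovery test therefore shows that the fitting machinery is correct and
  well-conditioned, not that effective connectivity of an arbitrary real
  circuit is identifiable.

## Reproducibility and the experiment runner

Every generator and initializer is a pure function of its arguments
including the seed. An experiment config carries a single seed that is
split deterministically into sub-seeds for task generation, weight
initialization and the trainer, so one component can be re-randomized by
changing one field. History CSVs contain epoch, train MAE, validation MAE
and update counts — wall times are kept only in memory — so re-running a
config reproduces artifacts byte-for-byte. Connectivity masks serialize
to Matrix Market (1-based, per that standard), weights to CSV bundles or
HDF5, tasks to CSV with a JSON sidecar; neuron indices are 0-based in all
CSV exports.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one core: oracle checks at
$N \le 100$, training-progress comparisons on the 801-step task with
400-neuron reservoirs over 10 epochs and 10 seeds, spiking closed forms
on single neurons at $\Delta t = \tau_m/10^4$, a 250-neuron theta network
on a 3 s Lorenz segment, and teacher-student recovery at $N = 50$,
$T = 500$ with the last 100 steps held out. The full-scale spiking
experiments (5000 neurons, $10^5$–$10^6$ steps) are outside the intended
scale of this implementation.

## Known limitations

* Recurrent classic-FORCE training is scalar-output only (per-neuron
  matrices are defined for one error signal); full-FORCE is the intended
  route for multi-dimensional targets.
* No batching: one trajectory at a time, by contract.
* No gradient-based training, no conductance synapses, no axonal delays,
  no GPU path.
* The spiking trainers learn decoders only; static recurrent spiking
  weights are never modified.

## A worked five-line session

```{r example, eval = FALSE}
task  <- gen_sum_of_sines()
layer <- init_rate_network(400, "nofeedback_esn", m_in = 2, m_out = 1,
                           gain = 1.5, seed = 1)
fit   <- force_fit(layer, task, training_config(epochs = 10))
tail(fit$history, 1)
predict(fit$layer, task)$mae
```
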