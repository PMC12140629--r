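---
title: "Uncertainty-modulated prediction errors in a layer 2/3 microcircuit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-modulated prediction errors in a layer 2/3 microcircuit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upecircuit)
```

## The model

An animal learns to predict a scalar sensory stimulus $s$ (a whisker
deflection) from a context cue $a$ (a tone, on/off).  Stimuli are drawn
from a context-specific Gaussian, $s \sim \mathcal N(\mu, \sigma)$.  The
maximum-likelihood update of an internal mean estimate $\hat\mu$ after
observing $s$ is

$$\Delta\hat\mu \propto \frac{s - \hat\mu}{\sigma^2},$$

the prediction error *scaled inversely by the variance*.  The package
simulates a rate-based layer 2/3 microcircuit that computes exactly this
kind of uncertainty-modulated prediction error (UPE) with identified
inhibitory cell types:

* **SST** interneurons inhibit the error neurons *subtractively* and
  carry the mean prediction (positive-error circuit) or the stimulus
  itself (negative-error circuit).
* **PV** interneurons inhibit *divisively*, integrate their input
  through a rectified-quadratic transfer $\phi_{PV}(x) = x^2$ (saturated
  at $x_{\max}$), and their cue-driven rate comes to encode the variance
  $\sigma^2$.
* **UPE** pyramidal neurons compare stimulus and prediction on a
  dendrite, $I_{dend} = \lfloor w\,s - w\,r_{SST}\rfloor_+^k$, and their
  somatic drive is divided by the PV rate,
  $I = I_{dend} / (I_0 + w\,r_{PV})$.  Positive and negative errors are
  carried by distinct populations since rates cannot go negative.

All populations follow leaky rate dynamics
$\tau \dot r = -r + \phi(I)$, integrated with forward Euler at
$dt = 0.1$; rates are rectified and saturate at $\phi(x_{\max})$
(we tie $r_{\max} = \phi(x_{\max})$ so that saturation is continuous —
the saturation value is otherwise a free constant).

### Learning

Every plastic weight runs the same local rule
$$\Delta w = \eta\,\bigl(r_{post} - \phi(w\,r_{pre})\bigr)\,r_{pre},$$
with $\phi$ the postsynaptic transfer.  During learning the teaching
signal *nudges* the interneuron's drive with factor $\beta$:
the SST drive is $(1-\beta)\,w_{SST,a}\,a + \beta s$, and the PV drive is
$(1-\beta)\,w_{PV,a}\,a + \beta\,w_s(s - r_{SST})$.  The nudging scales
the teaching variance down, so the fixed weights carrying the
mean-subtracted stimulus must be scaled up by
$$w_s = \sqrt{\tfrac{2-\beta}{\beta}},$$
which makes the PV cue weight converge to $\sigma$ (and its cue-driven
rate to $\sigma^2$).  The derivation replaces the rectified quadratic by
a pure quadratic; `run_beta_compensation_sweep()` verifies that the
recovery holds to 10% for $\beta \le 0.2$ and degrades beyond
$\beta = 0.5$.

The matching of inhibitory onto excitatory weights that EI balance
requires is handled by `balance_update()`, a target-based rule
$\Delta w = \eta\,r_{pre}\,(I_{exc} - I_{inh})$ whose fixed point is the
balance itself; only the fixed point is constrained by the model, the
trajectory is this package's choice.

### Circuit variants

`upe_circuit()` assembles four variants: the feedforward positive and
negative prediction-error circuits, the recurrent circuit in which a
representation neuron $R$ learns the mean through the difference of the
two error populations, and a two-area hierarchical circuit in which $R$
receives bottom-up UPEs (stimulus vs $R$, divided by the sensory
variance $\sigma_s^2$) and local UPEs ($R$ vs a prior $p$, divided by
the prior variance $\sigma_p^2$).  Its steady state is the
reliability-weighted average

$$r = \frac{s/\sigma_s^2 + p/\sigma_p^2}{1/\sigma_s^2 + 1/\sigma_p^2},$$

implemented in closed form as `steady_state_representation()` and used
as the oracle for the simulated circuit.

## Design choices in genuinely open places

These are places where the model as stated leaves the
implementation open; the package commits to one choice and documents it
here.

**The hierarchical representation neuron integrates.**  A leaky rate
equation for $R$ would add the leak to the denominator of the steady
state and could not reproduce the weighted-average fixed point.  The
representation update is therefore implemented as gradient dynamics on
the prediction-error energy: $\tau_E \dot r_R$ equals the difference
between bottom-up and local UPEs (rectified at zero), whose fixed point
is exactly the closed form above.  The integration runs `r_gain = 0.05`
times slower than the error populations relax.  The gain does not move
the fixed point; it keeps the loop (two interneuron/error lags plus an
integrator) overdamped for the smallest variances on the sweep grid.
Biologically it says the representation changes slowly relative to the
errors that drive it.

**Clamp mode fixes the denominator.**  In weighting sweeps the PV
activity "is" the variance, so the clamp sets the whole divisive
denominator to $\sigma^2$ and uses a linear dendrite ($k = 1$; the
energy whose gradient $R$ descends is quadratic, its errors linear).
With $I_0$ inside the denominator the steady state would be weighted by
$I_0 + \sigma^2$ instead of $\sigma^2$.

**Teaching drives are learning machinery.**  The $\beta$-nudged terms
exist to steer plasticity, so they are applied only on learning
timesteps.  During frozen probes the interneurons fire from the cue
alone: SST$^+$ reads out the learned mean, PV reads out the learned
variance — which is what makes the predicted PV rates of the positive
and negative circuits equal under mismatch.  (With the nudge left on, the
quadratic PV transfer would give $(a+b)^2$ in one circuit and $(a-b)^2$
in the other.)  Cue-only phases additionally silence the dendritic
comparison: a probe without a stimulus reads predictions, not errors.

**Probes read the converged circuit.**  `run_mismatch_probes()` probes
with the plastic weights at their training-window averages rather than
their last-step values.  The instantaneous weights jitter around the
fixed point (the SST cue weight by a few percent at $\eta_{SST} = 0.1$),
and a mismatch response to a 1-unit deviation is quadratic in that
jitter; the window average is the estimator of the converged state the
summaries already use.

**The learning-rate comparison isolates the principle.**  In
`run_learning_rate_comparison()` the modulated circuit's PV rate is
clamped at the condition's variance, so its effective learning rate is
$1/(I_0 + \sigma^2)$, and the unmodulated control divides by a constant
chosen as the mean of the two effective rates.  With freely evolving PV
rates the teaching input spikes during the mean transition (the error
enters the PV drive), which transiently suppresses the modulated
circuit and confounds the comparison of learning rates.  The error
neurons use a linear dendrite here ($k = 1$): the normative update this
protocol tests is linear in the prediction error, and a quadratic
dendrite makes the update size — and hence the representation's
standard deviation — grow supralinearly with $\sigma$, which is a
statement about the dendritic nonlinearity, not about uncertainty
modulation.

**Sample-hold duration per protocol.**  The stimulus generator holds
each sample for $D$ timesteps, with $D \in \{10, 100\}$ the sanctioned
choices.  Protocols whose teaching signal involves a *relayed* quantity
(the negative circuit's SST relays the stimulus; the recurrent PV
pathways compare two relayed rates) use $D = 100$ so the relays settle
within each hold; with $D = 10$ (one membrane time constant) the switch
transients systematically inflate the negative-side variance estimate.
The feedforward variance-learning and recurrent mean-learning
recoveries use $D = 10$, their standard protocol, and meet
their tolerances there.

**Other defaults.**  Where a protocol leaves its $\mu$ or $\sigma$
open: mean-learning runs use $\sigma = 0.5$,
variance-learning runs $\mu = 5$, the learning-rate conditions
$\sigma \in \{0.1, 0.8\}$, and mismatch magnitudes are $\pm 1$ stimulus
unit.  All are exposed in the protocol signatures and echoed in every
output.  $I_0$ defaults to 1.0: with rates nonnegative the denominator
never drops below 1, which is all the "division never amplifies"
requirement needs; the strict form $I_0 > 1$ is available through
configuration.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `dt` | 0.1 | Euler step (time units) |
| `tau_e`, `tau_i` | 1.0, 1.0 | membrane time constants (10, 2 in mismatch runs) |
| `beta` | 0.1 | nudging factor of teaching drives |
| `ws` | $\sqrt{(2-\beta)/\beta}$ | compensation scale on the nudged PV pathway |
| `k` | 2 | dendritic exponent (2.5 in steep-dendrite probes; 1 in normative-update protocols) |
| `I0` | 1.0 | divisive offset |
| `xmax` | 20 | saturation input of both transfers |
| `eta_sst`, `eta_pv`, `eta_r` | 0.1, 0.001, 0.1 | learning rates (`eta_r` 0.01 in mismatch runs) |
| `w_r_upe` | 0.1 | error-to-representation weight (1.0 in mismatch runs) |
| `w_init` | 0.01 | initial plastic weights |

## What the generator emulates — and what it does not

`upe_schedule()` reproduces the training protocol exactly: $N$
i.i.d. Gaussian samples per context, each held for $D$ timesteps while
the binary cue is on; step-change schedules concatenate epochs with a
shifted mean; probe schedules present fixed deviations with plasticity
frozen.  It does **not** emulate naturalistic stimulus statistics
(temporal correlations, heavy tails, multidimensional features), cue
ambiguity, or trial-to-trial gain changes.  Passing tests therefore
show that the circuit implements the claimed computation under the
model's own stimulus assumptions — not that the computation is robust
to real sensory statistics.

## Numerical choices and degenerate inputs

Forward Euler at `dt = 0.1` with synchronous updates (all drives are
computed from the previous step's rates); no adaptive stepping.  Rates
are clipped to $[0, r_{\max}]$ after each step, which coincides with the
saturating transfer.  Probe responses are read after
$100\,\tau_E/dt$ settling steps.  Convergence of a training run is
declared when the rolling mean of the plastic weight changes by less
than 1% over the final windows (each protocol documents its averaging
window; summaries report the final 20% of training unless stated).  A zero-length schedule returns an empty trace with the
initial state preserved; `NaN`/`Inf` stimulus values abort with the
offending timestep (use `NA` for "no stimulus"); invalid distributions
($\sigma \le 0$), empty grids and out-of-range $\beta$ fail fast with
named errors.

Problem sizes: variance-learning recoveries use $2\times10^5$
timesteps per condition, mean-representation recoveries $10^5$, the
weighting sweep a $5\times5$ variance grid with 5 stimuli per cell and
6000 settling steps per stimulus, and the learning-rate comparison
$10^6$ timesteps per arm and condition.  These sizes put every
stochastic recovery an order of magnitude inside its averaging window's
needs while keeping a full run in seconds of CPU time.

## Known limitations

* The mean-representation weight of the recurrent circuit converges a
  few percent above the trained mean at $D = 10$ (within its 10%
  tolerance): the relayed-stimulus transients excite the negative error
  pathway asymmetrically.  At $D = 100$ the bias drops below 1%.
* The positive circuit's variance estimate inherits a $(1-\beta)$
  contamination from the nudged SST rate, the negative circuit's does
  not; the predicted PV equality across circuits is therefore
  approximate (the protocols check agreement of the cue weights within
  25%).
* The hierarchical variant implements the two-area case with scalar
  inter-level weights only; no learning of those weights, no deeper
  stacks, no population codes.
* Rate-based, single-compartment dynamics throughout: no spiking, no
  conductances, no dendritic biophysics beyond the single rectified
  power law.

## A worked run

```{r example, eval = FALSE}
sch <- upe_schedule(upe_context(mu = 5, sigma = 0.8),
                    n_samples = 20000, duration = 10, seed = 1)
fit <- upe_train(upe_circuit("pe+"), sch)
coef(fit)                       # converged cue weights: ~5 and ~0.8
predict(fit, type = "readout")  # cue-only rates: mean and variance
predict(fit, newdata = c(5, 6), type = "response")  # probe responses
```
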