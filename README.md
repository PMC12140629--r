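# upecircuit

Rate-based simulation of layer 2/3 cortical microcircuits that compute
**uncertainty-modulated prediction errors (UPEs)**.  The package is for
computational neuroscientists who want a tested, scriptable
implementation of the circuit model in which somatostatin-positive
(SST) and parvalbumin-positive (PV) interneurons learn the mean and
variance of a context-cued Gaussian stimulus distribution through local
plasticity, and pyramidal error neurons report prediction errors
divided by the learned uncertainty.

## The model in brief

A context cue `a` (on/off) predicts a scalar stimulus
`s ~ N(mu, sigma)`.  The normative update of an internal mean estimate
is the variance-scaled error `(s - mu_hat) / sigma^2`.  The circuit
realises it with three cell types per error sign:

* SST (subtractive): drive `(1-beta) w_SST,a a + beta s`, learning
  `dw = eta (r_SST - phi(w a)) a`  →  `w_SST,a → mu`;
* PV (divisive, quadratic transfer `phi_PV(x) = x^2`): drive
  `(1-beta) w_PV,a a + beta w_s (s - r_SST)` with compensation
  `w_s = sqrt((2-beta)/beta)`  →  `w_PV,a → sigma`, cue-driven rate
  `→ sigma^2`;
* UPE pyramidal neurons:
  `tau_E dr/dt = -r + phi( |_ w s - w r_SST _|+^k / (I0 + w r_PV) )`.

A recurrent variant adds a representation neuron `R` updated by
`UPE+ - UPE-` (its cue weight learns `mu`); a two-area hierarchical
variant weights stimulus against prior by their variances, settling at
`r = (s/sigma_s^2 + p/sigma_p^2) / (1/sigma_s^2 + 1/sigma_p^2)`.

## Worked example

Train the positive prediction-error circuit on a high-uncertainty
context and read out what it learned:

```r
library(upecircuit)
sch <- upe_schedule(upe_context(mu = 5, sigma = 0.8),
                    n_samples = 20000, duration = 10, seed = 1)
fit <- upe_train(upe_circuit("pe+"), sch)
fit
#> Trained 'pe+' circuit: 200000 timesteps (D = 10, seed = 1)
#> Converged weights (mean over final 20% of training):
#> w_sst_a  w_pv_a
#>  5.0141  0.7763
```

The cue-to-SST weight converged to the stimulus mean (5) and the
cue-to-PV weight to its standard deviation (0.8).  Cue-only readout and
mismatch probes:

```r
predict(fit, type = "readout")
#>   context_id mu_hat sd_hat rate_mean rate_var
#> 1          1   4.93 0.7746      4.93   0.5999

predict(fit, newdata = c(5, 6), type = "response")
#>   s SST+ PV+    UPE+
#> 1 5 4.93 0.6 0.00307
#> 2 6 4.93 0.6 0.71565
```

Under the cue alone, the PV rate reports the learned variance
(0.60 ≈ 0.8²).  An expected stimulus (s = 5) leaves the error neuron
silent; a +1 mismatch drives it at `1 / (I0 + sigma^2)` ≈ 0.72 — the
same deviation in a low-uncertainty context would drive it harder.

Scripted protocols reproduce the full computational experiments:
`run_mean_learning()`, `run_variance_learning()`,
`run_mismatch_probes()`, `run_learning_rate_comparison()`,
`run_bayes_weighting_sweep()`, `run_beta_compensation_sweep()`.  Each
returns tables plus named pass/fail checks of the claimed property.  A
thin command-line interface wraps them (`exec/upe`, see
`upe_main()`).

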