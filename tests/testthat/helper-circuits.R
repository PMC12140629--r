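# shared fixtures: everything is generated in code at test time

quick_schedule <- function(mu = 5, sigma = 0.5, n = 500, seed = 1, D = 10) {
  upe_schedule(upe_context(mu, sigma), n_samples = n, duration = D,
               seed = seed)
}

# a fit whose plastic weights are pinned to given values (rates zeroed),
# for probing circuits with known weights
pinned_fit <- function(circuit, weights) {
  init <- list(rates = NULL, weights = weights)
  f <- upe_train(circuit, upe_cue_schedule(1), thin = 1, init = init,
                 learn_override = FALSE)
  f
}
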