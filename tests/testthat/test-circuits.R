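test_that("circuit builders wire the right populations and validate input", {
  expect_identical(upe_circuit("pe+")$populations, c("SST+", "PV+", "UPE+"))
  expect_identical(upe_circuit("recurrent")$plastic,
                   c("w_r_a", "w_pv_p_a", "w_pv_m_a"))
  expect_error(upe_circuit("pe-"), "prediction")
  expect_error(upe_circuit("hierarchical"), "sigma_s2")
  expect_error(upe_circuit("hierarchical",
                           clamp = list(sigma_s2 = -1, sigma_p2 = 1,
                                        prior = 2)), "variances")
  expect_error(upe_circuit("pe+", params = list()), "upe_params")
  expect_output(print(upe_circuit("pe-", clamp = list(prediction = 5))),
                "pe-")
})

test_that("perfectly predicted stimuli silence the error neuron exactly", {
  # SST+ pinned at the stimulus value: dendritic drive is zero, UPE+ = 0
  circuit <- upe_circuit("pe+")
  f0 <- pinned_fit(circuit, list(w_sst_a = 5, w_pv_a = 0.4))
  resp <- predict(f0, newdata = 5, type = "response")
  expect_equal(resp[["UPE+"]], 0, tolerance = 1e-8)
  expect_equal(resp[["SST+"]], 5, tolerance = 1e-6)
  # and the cue-driven PV rate reads out the learned variance
  expect_equal(resp[["PV+"]], 0.16, tolerance = 1e-6)
})

test_that("positive and negative circuits split the error by sign", {
  p <- upe_params()
  fp <- pinned_fit(upe_circuit("pe+", p), list(w_sst_a = 5, w_pv_a = 0.3))
  fm <- pinned_fit(upe_circuit("pe-", p, clamp = list(prediction = 5)),
                   list(w_pv_a = 0.3))
  below <- 4  # stimulus one unit below the prediction
  rp <- predict(fp, newdata = below, type = "response")
  rm <- predict(fm, newdata = below, type = "response")
  expect_equal(rp[["UPE+"]], 0, tolerance = 1e-8)
  expect_gt(rm[["UPE-"]], 0.5)
  # negative-circuit SST relays the stimulus itself
  expect_equal(rm[["SST-"]], below, tolerance = 1e-6)
  # equal learned weights give equal cue-driven PV rates in both circuits
  expect_equal(rp[["PV+"]], rm[["PV-"]], tolerance = 1e-8)
})

test_that("uncertainty divides the error response", {
  # same mismatch, larger learned sigma, smaller UPE+ response;
  # steady state follows dend / (I0 + pv) through the saturating transfer
  circuit <- upe_circuit("pe+")
  resp <- vapply(c(0.2, 0.4, 0.8, 1.2), function(sg) {
    f <- pinned_fit(circuit, list(w_sst_a = 5, w_pv_a = sg))
    predict(f, newdata = 6, type = "response")[["UPE+"]]
  }, numeric(1))
  expect_true(all(diff(resp) < 0))
  expect_equal(resp[1], 1 / (1 + 0.04), tolerance = 1e-6)
})

test_that("recurrent circuit reaches a stationary balanced state", {
  sch <- quick_schedule(mu = 4, sigma = 0.5, n = 5000, seed = 13, D = 10)
  fit <- upe_train(upe_circuit("recurrent"), sch)
  tr <- fit$traces
  last <- tr[tr$t > 0.8 * max(tr$t), ]
  # positive and negative errors balance on average and R is stationary
  expect_lt(abs(mean(last[["UPE+"]]) - mean(last[["UPE-"]])),
            0.2 * max(mean(last[["UPE+"]]), 0.05))
  expect_lt(abs(mean(last$R) - 4) / 4, 0.1)
  drift <- abs(mean(last$R[seq_len(nrow(last) %/% 2)]) -
                 mean(last$R[-seq_len(nrow(last) %/% 2)]))
  expect_lt(drift / 4, 0.02)
  # cue-only readout reports the learned mean through R
  ro <- predict(fit, type = "readout")
  expect_lt(abs(ro$rate_mean - 4) / 4, 0.1)
})

test_that("closed-form representation weighting and its limits", {
  expect_equal(steady_state_representation(2, 1, 1, 1), 1.5)
  expect_equal(steady_state_representation(2, 1, 0.5, 1), 5 / 3)
  expect_equal(steady_state_representation(2, 1, 0.5, 1e9), 2,
               tolerance = 1e-6)
  expect_equal(steady_state_representation(2, 1, 1e9, 0.5), 1,
               tolerance = 1e-6)
  expect_error(steady_state_representation(2, 1, 0, 1), "variances")
})

test_that("hierarchical circuit matches the weighting oracle", {
  p <- upe_params()
  run_r <- function(s, ss, pp, prior = 3) {
    circuit <- upe_circuit("hierarchical", p,
                           clamp = list(sigma_s2 = ss, sigma_p2 = pp,
                                        prior = prior))
    f <- upe_train(circuit, upe_probe_schedule(s, 0, duration = 6000),
                   thin = 6000)
    f$final$rates[["R"]]
  }
  # equal uncertainties average stimulus and prior
  expect_equal(run_r(5, 0.5, 0.5), 4, tolerance = 0.02)
  # an uninformative prior hands the representation to the stimulus
  expect_equal(run_r(5, 0.5, 50), 5, tolerance = 0.05)
  # an uninformative likelihood hands it to the prior
  expect_equal(run_r(5, 50, 0.5), 3, tolerance = 0.05)
  # general cell against the closed form
  expect_equal(run_r(4.2, 0.7, 1.3),
               steady_state_representation(4.2, 3, 0.7, 1.3),
               tolerance = 0.01)
})

test_that("simulation is deterministic and handles degenerate schedules", {
  sch <- quick_schedule(n = 200, seed = 5)
  f1 <- upe_train(upe_circuit("pe+"), sch)
  f2 <- upe_train(upe_circuit("pe+"), sch)
  expect_identical(f1$traces, f2$traces)
  expect_identical(f1$final, f2$final)
  # zero-length schedule: empty trace, initial state preserved
  empty <- sch[0, ]
  attr(empty, "contexts") <- attr(sch, "contexts")
  attr(empty, "duration") <- attr(sch, "duration")
  class(empty) <- class(sch)
  init <- list(weights = list(w_sst_a = 2, w_pv_a = 0.5))
  f0 <- upe_train(upe_circuit("pe+"), empty, init = init)
  expect_identical(nrow(f0$traces), 0L)
  expect_equal(f0$final$weights$w_sst_a, 2)
  expect_equal(f0$final$rates[["SST+"]], 0)
})

test_that("non-finite stimuli abort with a diagnostic", {
  bad <- upe_probe_schedule(5, c(0, NaN), duration = 5)
  bad$s[6:10] <- Inf
  expect_error(upe_train(upe_circuit("pe+"), bad), "timestep|finite")
})
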