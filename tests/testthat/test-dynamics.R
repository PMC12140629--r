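test_that("activation functions: rectification, identity/square, saturation", {
  expect_equal(phi(c(-1, 0, 5, 19.9, 25)), c(0, 0, 5, 19.9, 20))
  expect_equal(phi_pv(c(-2, 0.4, 0.8, 25)), c(0, 0.16, 0.64, 400))
  # saturation is continuous: phi(xmax - eps) -> rmax
  expect_equal(phi(20 - 1e-9), 20, tolerance = 1e-8)
  expect_equal(phi_pv(20 - 1e-7), 400, tolerance = 1e-4)
  sp <- activation_spec("rectified-quadratic", xmax = 2)
  expect_equal(sp$rmax, 4)
  expect_error(activation_spec(xmax = -1), "xmax")
})

test_that("dendritic current rectifies and raises to the exponent", {
  expect_equal(dendritic_current(2, 1, k = 2), 1)
  expect_equal(dendritic_current(1, 2, k = 2), 0)
  expect_equal(dendritic_current(1, 2, k = 7), 0)
  expect_equal(dendritic_current(2, 0.5, k = 2.5), 1.5^2.5)  # ~2.7557
  expect_error(dendritic_current(1, 0, k = 0.5), "k")
})

test_that("divisive modulation never amplifies and is monotone", {
  expect_equal(upe_drive(1, pv_rate = 0), 1)
  expect_equal(upe_drive(1, pv_rate = 0.64), 1 / 1.64)
  pv <- seq(0, 5, 0.5)
  out <- upe_drive(1, pv)
  expect_true(all(diff(out) < 0))
  expect_true(all(out <= 1))  # I0 >= 1 guarantees no amplification
  expect_error(upe_drive(1, pv_rate = -2, w_div = 1, I0 = 1), "positive")
})

test_that("Euler step relaxes to phi(I) and respects bounds", {
  specs <- list(
    E = list(tau = 1, activation = activation_spec("rectified-linear")),
    P = list(tau = 0.5, activation = activation_spec("rectified-quadratic")))
  r <- c(E = 0, P = 0)
  # single-step arithmetic: r <- r + dt/tau (-r + phi(I))
  one <- euler_step(r, c(E = 1, P = 1), dt = 0.1, specs)
  expect_equal(one[["E"]], 0.1)
  expect_equal(one[["P"]], 0.2)
  # fixed point r = phi(I) for constant input after 100 tau / dt steps
  for (i in seq_len(1000)) r <- euler_step(r, c(E = 3, P = 0.7), 0.1, specs)
  expect_equal(r[["E"]], 3, tolerance = 1e-6)
  expect_equal(r[["P"]], 0.49, tolerance = 1e-6)
  # zero input, zero rate stays put
  expect_equal(euler_step(c(E = 0, P = 0), c(E = 0, P = 0), 0.1, specs),
               c(E = 0, P = 0))
  expect_error(euler_step(r, c(E = NaN, P = 0), 0.1, specs), "E")
})

test_that("rates stay in [0, rmax] under arbitrary bounded inputs", {
  specs <- list(E = list(tau = 1,
                         activation = activation_spec("rectified-linear")))
  set.seed(42)
  r <- c(E = 0)
  for (i in seq_len(500)) {
    r <- euler_step(r, c(E = runif(1, -50, 50)), dt = 0.1, specs)
    expect_gte(r[["E"]], 0)
    expect_lte(r[["E"]], 20)
  }
})

test_that("compiled integration matches the reference Euler step", {
  # cue-only run of the positive circuit with pinned weights: SST+ and
  # PV+ relax towards phi(w a); compare the compiled trace against the
  # same recursion computed with euler_step()
  p <- upe_params()
  fit <- upe_train(upe_circuit("pe+", p), upe_cue_schedule(200), thin = 1,
                   init = list(weights = list(w_sst_a = 3, w_pv_a = 0.8)),
                   learn_override = FALSE)
  specs <- list(
    sst = list(tau = p$tau_i, activation = activation_spec("rectified-linear",
                                                           p$xmax)),
    pv = list(tau = p$tau_i, activation = activation_spec(
      "rectified-quadratic", p$xmax)))
  r <- c(sst = 0, pv = 0)
  ref <- matrix(NA_real_, 200, 2)
  for (i in seq_len(200)) {
    r <- euler_step(r, c(sst = 3, pv = 0.8), p$dt, specs)
    ref[i, ] <- r
  }
  expect_equal(fit$traces[["SST+"]], ref[, 1], tolerance = 1e-12)
  expect_equal(fit$traces[["PV+"]], ref[, 2], tolerance = 1e-12)
  expect_equal(fit$final$rates[["PV+"]], 0.64, tolerance = 1e-6)
})
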