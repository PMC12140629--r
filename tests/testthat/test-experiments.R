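test_that("mean learning recovers the identity line over the mu grid", {
  ex <- run_mean_learning(seed = 2)
  tab <- ex$tables$conditions
  expect_equal(tab$mu, c(1, 3, 5))
  expect_true(all(abs(tab$w_sst_a - tab$mu) / pmax(tab$mu, 1) < 0.1))
  expect_true(ex$checks$identity_slope)
  expect_true(ex$checks$identity_intercept)
  # SST rate mirrors the weight (cue drive through a linear transfer)
  expect_true(all(abs(tab$sst_rate - tab$w_sst_a) < 0.05))
  # a zero mean trains a silent prediction
  ex0 <- run_mean_learning(mu_grid = 0, sigma = 0.2, n_samples = 500,
                           seed = 4)
  expect_lt(abs(ex0$tables$conditions$w_sst_a), 0.1)
})

test_that("variance learning stores sigma in the weight, sigma^2 in the rate", {
  ex <- run_variance_learning(seed = 2)
  tab <- ex$tables$conditions
  expect_true(all(abs(tab$w_pv_a - tab$sigma) / tab$sigma <= 0.1))
  expect_true(all(abs(tab$pv_rate_cue - tab$sigma^2) / tab$sigma^2 <= 0.25))
  expect_lt(tab$w_pv_a[1], tab$w_pv_a[2])
  expect_true(all(unlist(ex$checks)))
})

test_that("protocols are deterministic given config and seed", {
  a <- run_mean_learning(n_samples = 300, seed = 9)
  b <- run_mean_learning(n_samples = 300, seed = 9)
  expect_identical(a$tables, b$tables)
  expect_identical(a$checks, b$checks)
})

test_that("mismatch probes follow the cell-type predictions", {
  ex <- run_mismatch_probes(seed = 11, n_samples = 4000)
  tab <- ex$tables$responses
  expect_true(all(unlist(ex$checks)))
  # deviations below prediction drive only the negative circuit
  neg <- tab[tab$deviation < 0, ]
  expect_true(all(neg[["UPE-"]] > 0.1 & neg[["UPE+"]] < 1e-6))
  pos <- tab[tab$deviation > 0, ]
  expect_true(all(pos[["UPE+"]] > 0.1 & pos[["UPE-"]] < 1e-6))
})

test_that("a steeper dendrite amplifies large errors relative to small", {
  sig <- c(0.4, 0.8)
  r_for <- function(k) {
    ex <- run_mismatch_probes(sigmas = sig, deviations = c(1, 2), k = k,
                              n_samples = 4000, seed = 11)
    tab <- ex$tables$responses
    tab[["UPE+"]][tab$deviation == 2] / tab[["UPE+"]][tab$deviation == 1]
  }
  expect_true(all(r_for(2.5) > r_for(2)))
})

test_that("uncertainty modulation yields an adaptive effective rate", {
  ex <- run_learning_rate_comparison(seed = 5, samples_per_epoch = 3000)
  cmp <- ex$tables$comparison
  expect_true(ex$checks$faster_when_certain)
  expect_true(ex$checks$steadier_when_uncertain)
  expect_true(ex$checks$sublinear_sd)
  expect_lt(cmp$eff_rate_upe[2], cmp$gain_control[1])
  # no variability without stimulus noise: sd curve rises from ~0
  expect_true(all(diff(ex$tables$sd_curve$sd_r) > 0))
})

test_that("hierarchical sweep matches the weighting oracle per cell", {
  ex <- run_bayes_weighting_sweep(sigma_s2_grid = c(0.5, 1.5),
                                  sigma_p2_grid = c(0.5, 1.5))
  expect_lte(max(ex$tables$grid$max_rel_err), 0.02)
  expect_true(all(ex$tables$grid$slope < 1))
  # extreme prior uncertainty: slope approaches 1
  wide <- run_bayes_weighting_sweep(sigma_s2_grid = 0.3,
                                    sigma_p2_grid = 100)
  expect_gt(wide$tables$grid$slope, 0.98)
  narrow <- run_bayes_weighting_sweep(sigma_s2_grid = 100,
                                      sigma_p2_grid = 0.3)
  expect_lt(narrow$tables$grid$slope, 0.02)
  expect_equal(mean(narrow$tables$points$r_sim), 3, tolerance = 0.02)
})

test_that("compensation sweep recovers sigma only for small beta", {
  ex <- run_beta_compensation_sweep(beta_grid = c(0.1, 0.8),
                                    n_samples = 8000, seed = 9)
  tab <- ex$tables$conditions
  expect_lte(tab$rel_err[tab$beta == 0.1], 0.1)
  expect_gt(tab$rel_err[tab$beta == 0.8], 0.1)
})

test_that("maximum-likelihood update oracle", {
  expect_equal(ml_mean_update(5, 5, 1), 0)
  expect_equal(ml_mean_update(6, 5, 2, eta = 1), 0.5)
  expect_error(ml_mean_update(1, 1, 0), "sigma2")
  # stochastic approximation converges, with variance shrinking in eta
  run <- function(eta) {
    set.seed(12)
    mu_hat <- 0
    trace <- numeric(4000)
    for (i in seq_along(trace)) {
      mu_hat <- mu_hat + ml_mean_update(rnorm(1, 3, 0.5), mu_hat, 0.25,
                                        eta = eta * 0.25)
      trace[i] <- mu_hat
    }
    trace
  }
  slow <- run(0.02); fast <- run(0.2)
  expect_lt(abs(mean(tail(slow, 1000)) - 3), 0.1)
  expect_lt(sd(tail(slow, 1000)), sd(tail(fast, 1000)))
})
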