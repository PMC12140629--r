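new_experiment <- function(protocol, config, tables, checks,
                           notes = character(0)) {
  structure(list(protocol = protocol, config = config, tables = tables,
                 checks = checks, notes = notes),
            class = "upe_experiment")
}

#' @export
print.upe_experiment <- function(x, ...) {
  cat(sprintf("Protocol '%s'\n", x$protocol))
  cfg <- x$config
  cat("  config:", paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), ""), sep = "=", collapse = "  "), "\n")
  for (nm in names(x$tables)) {
    cat(sprintf("-- %s --\n", nm))
    print(x$tables[[nm]], digits = 4, row.names = FALSE)
  }
  if (length(x$checks)) {
    ok <- unlist(x$checks)
    cat("checks:", paste(sprintf("%s[%s]", names(ok),
                                 ifelse(ok, "pass", "FAIL")),
                         collapse = " "), "\n")
  }
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}

# relative drift of the rolling mean of a weight trace over its final
# windows; the convergence criterion of all training protocols
weight_drift <- function(fit, col, window = 0.1) {
  tr <- fit$traces[startsWith(fit$traces$phase, "train"), , drop = FALSE]
  n <- nrow(tr)
  if (n < 10L) return(NA_real_)
  w <- max(2L, ceiling(window * n))
  last <- mean(tr[[col]][(n - w + 1L):n])
  prev <- mean(tr[[col]][(n - 2L * w + 1L):(n - w)])
  abs(last - prev) / max(abs(last), 1e-12)
}

#' Mean-learning protocol
#'
#' Trains the positive prediction-error circuit on one Gaussian context
#' per grid value of the mean and reads out the converged cue-to-SST
#' weight and the SST firing rate: both should lie on the identity line
#' against the trained mean.
#'
#' @param mu_grid means to train on; default `c(1, 3, 5)`.
#' @param sigma shared standard deviation; default 0.5.
#' @param n_samples stimulus samples per condition; default 1000.
#' @param duration hold time per sample (timesteps); default 10.
#' @param seed integer seed (one independent schedule per condition).
#' @param params an [upe_params()]; default the standard operating point.
#' @param window averaging window (fraction of training, from the end);
#'   default 0.1 (the final tenth of the run).
#' @return an object of class `upe_experiment`; table `conditions` has
#'   one row per mean with the converged weight, SST rate and a
#'   convergence flag, table `fitline` the identity-line regression.
#' @export
run_mean_learning <- function(mu_grid = c(1, 3, 5), sigma = 0.5,
                              n_samples = 1000, duration = 10, seed,
                              params = upe_params(), window = 0.1) {
  if (length(mu_grid) == 0L) stop("invalid argument: empty grid")
  if (missing(seed)) stop("'seed' is required")
  rows <- lapply(seq_along(mu_grid), function(i) {
    sch <- upe_schedule(upe_context(mu_grid[i], sigma), n_samples, duration,
                        seed = seed + i - 1L)
    fit <- upe_train(upe_circuit("pe+", params), sch)
    data.frame(mu = mu_grid[i],
               w_sst_a = coef(fit, window)[["w_sst_a"]],
               sst_rate = window_stat(fit, "SST+", window),
               sst_rate_sd = window_stat(fit, "SST+", window, stat = sd),
               drift = weight_drift(fit, "w_sst_a"),
               converged = weight_drift(fit, "w_sst_a") < 0.01)
  })
  tab <- do.call(rbind, rows)
  fitline <- if (nrow(tab) >= 2) coef(lm(w_sst_a ~ mu, data = tab))
             else c(`(Intercept)` = NA_real_, mu = NA_real_)
  checks <- list(
    identity_slope = nrow(tab) < 2 ||
      (fitline[["mu"]] > 0.9 && fitline[["mu"]] < 1.1),
    identity_intercept = nrow(tab) < 2 || abs(fitline[["(Intercept)"]]) <= 0.1,
    converged = all(tab$converged, na.rm = TRUE))
  new_experiment("mean_learning",
                 list(mu_grid = mu_grid, sigma = sigma,
                      n_samples = n_samples, duration = duration,
                      seed = seed, window = window),
                 list(conditions = tab,
                      fitline = data.frame(slope = fitline[["mu"]],
                                           intercept = fitline[["(Intercept)"]])),
                 checks)
}

#' Variance-learning protocol
#'
#' Trains the positive prediction-error circuit per value of the stimulus
#' standard deviation and reads out the converged cue-to-PV weight (which
#' should approach sigma), the cue-only PV rate (which should approach
#' sigma^2) and the PV rate during paired cue and stimulus input.
#'
#' @param sigma_grid standard deviations; default `c(0.4, 0.8)`.
#' @param mu shared mean; default 5.
#' @param n_samples samples per condition; default 20000 (2e5 timesteps
#'   at `duration = 10`).
#' @param window averaging window; default 0.2.
#' @inheritParams run_mean_learning
#' @return an `upe_experiment` with table `conditions` (per sigma:
#'   converged weight, cue-only and stimulus-period PV rates).
#' @export
run_variance_learning <- function(sigma_grid = c(0.4, 0.8), mu = 5,
                                  n_samples = 20000, duration = 10, seed,
                                  params = upe_params(), window = 0.2) {
  if (length(sigma_grid) == 0L) stop("invalid argument: empty grid")
  if (missing(seed)) stop("'seed' is required")
  rows <- lapply(seq_along(sigma_grid), function(i) {
    sg <- sigma_grid[i]
    sch <- upe_schedule(upe_context(mu, sg), n_samples, duration,
                        seed = seed + i - 1L)
    fit <- upe_train(upe_circuit("pe+", params), sch)
    ro <- predict(fit, type = "readout")
    data.frame(sigma = sg, w_pv_a = coef(fit, window)[["w_pv_a"]],
               pv_rate_cue = ro$rate_var,
               pv_rate_stim = window_stat(fit, "PV+", window),
               drift = weight_drift(fit, "w_pv_a"),
               converged = weight_drift(fit, "w_pv_a") < 0.01)
  })
  tab <- do.call(rbind, rows)
  rel_err <- abs(tab$w_pv_a - tab$sigma) / tab$sigma
  checks <- list(
    weight_tracks_sigma = all(rel_err <= 0.1),
    cue_rate_tracks_var =
      all(abs(tab$pv_rate_cue - tab$sigma^2) / tab$sigma^2 <= 0.25),
    ordered = all(diff(tab$w_pv_a[order(tab$sigma)]) > 0) ||
      length(sigma_grid) < 2,
    converged = all(tab$converged, na.rm = TRUE))
  new_experiment("variance_learning",
                 list(sigma_grid = sigma_grid, mu = mu,
                      n_samples = n_samples, duration = duration,
                      seed = seed, window = window),
                 list(conditions = tab), checks)
}

#' Mismatch-probe protocol
#'
#' Trains the positive and the negative feedforward prediction-error
#' circuit per uncertainty condition and then presents mismatch stimuli
#' `s = mu + deviation` with plasticity frozen, reading out steady-state
#' rates of every cell type.  Error responses should shrink as the
#' trained uncertainty grows (the divisive PV input encodes the learned
#' variance); SST- should track the stimulus; the cue-driven PV rates of
#' the positive and negative subcircuits should agree.
#'
#' @param sigmas trained standard deviations (uncertainty conditions);
#'   default `c(0.4, 0.8)` (low/high).
#' @param mu trained mean; default 5.
#' @param deviations probe mismatches `s - mu`; default `c(-1, 0, 1)`.
#' @param k dendritic exponent of the error neurons; default 2.
#' @param n_samples training samples before probing; default 10000.
#' @param duration hold time per sample; default 100 here (long relative
#'   to `tau_i`, so the negative circuit's relayed stimulus settles
#'   within each hold).
#' @inheritParams run_mean_learning
#' @return an `upe_experiment`; table `responses` has one row per
#'   (sigma, deviation) with steady-state rates of SST+/-, PV+/-,
#'   UPE+/- and the converged cue weights.
#' @export
run_mismatch_probes <- function(sigmas = c(0.4, 0.8), mu = 5,
                                deviations = c(-1, 0, 1), k = 2,
                                n_samples = 10000, duration = 100, seed,
                                params = upe_params(k = k), window = 0.2) {
  if (length(deviations) == 0L) stop("invalid argument: empty deviation list")
  if (missing(seed)) stop("'seed' is required")
  rows <- list()
  for (i in seq_along(sigmas)) {
    sg <- sigmas[i]
    sch <- upe_schedule(upe_context(mu, sg), n_samples, duration,
                        seed = seed + i - 1L)
    fit_p <- upe_train(upe_circuit("pe+", params), sch)
    fit_m <- upe_train(upe_circuit("pe-", params,
                                   clamp = list(prediction = mu)), sch)
    # probe the converged circuit: plastic weights at their
    # training-window averages, not the jittering last-step values
    fit_p$final$weights$w_sst_a[1] <- coef(fit_p, window)[["w_sst_a"]]
    fit_p$final$weights$w_pv_a[1] <- coef(fit_p, window)[["w_pv_a"]]
    fit_m$final$weights$w_pv_a[1] <- coef(fit_m, window)[["w_pv_a"]]
    rp <- predict(fit_p, newdata = mu + deviations, type = "response")
    rm <- predict(fit_m, newdata = mu + deviations, type = "response")
    rows[[i]] <- data.frame(
      sigma = sg, deviation = deviations, s = rp$s,
      `SST+` = rp[["SST+"]], `PV+` = rp[["PV+"]], `UPE+` = rp[["UPE+"]],
      `SST-` = rm[["SST-"]], `PV-` = rm[["PV-"]], `UPE-` = rm[["UPE-"]],
      w_sst_a = coef(fit_p, window)[["w_sst_a"]],
      w_pv_p = coef(fit_p, window)[["w_pv_a"]],
      w_pv_m = coef(fit_m, window)[["w_pv_a"]],
      check.names = FALSE)
  }
  tab <- do.call(rbind, rows)
  zero <- tab[tab$deviation == 0, ]
  # strictly decreasing response across the sorted sigma grid, per probe
  strictly_falls <- function(col, devs) {
    if (length(devs) == 0L || length(sigmas) < 2L) return(TRUE)
    all(vapply(devs, function(d) {
      resp <- tab[tab$deviation == d, ]
      all(diff(resp[[col]][order(resp$sigma)]) < 0)
    }, logical(1)))
  }
  checks <- list(
    silent_at_zero = nrow(zero) == 0L ||
      all(zero[["UPE+"]] < 0.05 & zero[["UPE-"]] < 0.05),
    upe_pos_shrinks_with_uncertainty =
      strictly_falls("UPE+", deviations[deviations > 0]),
    upe_neg_shrinks_with_uncertainty =
      strictly_falls("UPE-", deviations[deviations < 0]),
    sst_minus_tracks_stimulus = all(abs(tab[["SST-"]] - tab$s) <
                                      0.05 * pmax(tab$s, 1)),
    pv_similar_across_circuits = all(abs(tab$w_pv_p - tab$w_pv_m) <=
                                       0.25 * pmax(tab$w_pv_p, tab$w_pv_m)))
  new_experiment("mismatch_probes",
                 list(sigmas = sigmas, mu = mu, deviations = deviations,
                      k = k, n_samples = n_samples, duration = duration,
                      seed = seed, window = window),
                 list(responses = tab), checks)
}

moving_average <- function(x, w) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))
}

# first recorded timestep after `after` at which the trailing moving
# average of the representation rate enters a +/-10% band around `target`
convergence_time <- function(fit, target, after, w = 50L) {
  tr <- fit$traces
  ma <- moving_average(tr[["R"]], w)
  ok <- which(tr$t > after & !is.na(ma) & abs(ma - target) <= 0.1 * target)
  if (length(ok) == 0L) return(NA_real_)
  tr$t[ok[1L]] - after
}

#' Adaptive-learning-rate comparison
#'
#' Compares the recurrent circuit against an unmodulated control on
#' identical step-change schedules in a low- and a high-uncertainty
#' context.  The PV activity of the modulated circuit is clamped at the
#' condition's variance (the idealised variance representation), so its
#' effective learning rate is `1/(I0 + w_div * sigma^2)`; the control
#' replaces the divisive denominator by a constant giving it the mean of
#' the two effective learning rates, per condition-blind design.  Also
#' measures how the steady-state variability of the representation grows
#' with the stimulus standard deviation.
#'
#' @param sigma_low,sigma_high the two uncertainty conditions; defaults
#'   0.1 and 0.8.
#' @param step_means epoch means of the step schedule; default `c(1, 5)`.
#' @param samples_per_epoch samples per epoch; default 5000.
#' @param duration hold time per sample; default 100 here, so the
#'   relayed stimulus (and hence the learned variance) settles within
#'   each hold and the PV rate separates the two uncertainty conditions.
#' @param sigma_grid standard deviations for the variability curve;
#'   default `c(0.1, 0.2, 0.4, 0.8, 1.2)`.
#' @param params circuit parameters; default `upe_params(k = 1)` — the
#'   effective-learning-rate analysis addresses the normative update,
#'   which is linear in the prediction error, so the error neurons use a
#'   linear dendrite here (as in the hierarchical circuit).
#' @inheritParams run_mean_learning
#' @return an `upe_experiment` with tables `comparison` (per condition:
#'   convergence time and steady-state sd of the representation for the
#'   modulated circuit and the control) and `sd_curve` (sd of the
#'   representation rate vs stimulus sd, with the log-log slope).
#' @export
run_learning_rate_comparison <- function(sigma_low = 0.1, sigma_high = 0.8,
                                         step_means = c(1, 5),
                                         samples_per_epoch = 5000,
                                         duration = 100, seed,
                                         sigma_grid = c(0.1, 0.2, 0.4, 0.8, 1.2),
                                         params = upe_params(k = 1),
                                         window = 0.2) {
  if (missing(seed)) stop("'seed' is required")
  if (length(step_means) < 2L) stop("invalid argument: need >= 2 means")
  t_change <- (length(step_means) - 1L) * samples_per_epoch * duration
  target <- step_means[length(step_means)]

  run_one <- function(sg, circuit, sd_seed) {
    sch <- upe_step_schedule(step_means, sg, samples_per_epoch, duration,
                             seed = sd_seed)
    upe_train(circuit, sch)
  }
  conds <- c(low = sigma_low, high = sigma_high)
  # PV clamped at the condition's variance: effective rate 1/(I0 + w s^2)
  eff_rate <- 1 / (params$I0 + params$w_div * as.numeric(conds)^2)
  upe_fits <- lapply(seq_along(conds), function(i)
    run_one(conds[i], upe_circuit("recurrent", params,
                                  clamp = list(gain = eff_rate[i])),
            seed + i - 1L))
  gain_ctrl <- mean(eff_rate)
  ctrl_fits <- lapply(seq_along(conds), function(i)
    run_one(conds[i], upe_circuit("recurrent", params,
                                  clamp = list(gain = gain_ctrl)),
            seed + i - 1L))

  stat_row <- function(f) {
    tr <- f$traces
    last <- tr[tr$t > t_change + 0.6 * (max(tr$t) - t_change), , drop = FALSE]
    c(t_conv = convergence_time(f, target, t_change),
      sd_r = sd(last[["R"]]))
  }
  su <- t(vapply(upe_fits, stat_row, numeric(2)))
  sc <- t(vapply(ctrl_fits, stat_row, numeric(2)))
  comparison <- data.frame(
    condition = names(conds), sigma = as.numeric(conds),
    eff_rate_upe = eff_rate, gain_control = gain_ctrl,
    t_conv_upe = su[, "t_conv"], t_conv_ctrl = sc[, "t_conv"],
    sd_r_upe = su[, "sd_r"], sd_r_ctrl = sc[, "sd_r"])

  sd_rows <- vapply(seq_along(sigma_grid), function(i) {
    sch <- upe_schedule(upe_context(target, sigma_grid[i]),
                        samples_per_epoch, duration, seed = seed + 10L + i)
    f <- upe_train(upe_circuit("recurrent", params,
                               clamp = list(gain = 1 / (params$I0 +
                                 params$w_div * sigma_grid[i]^2))), sch)
    window_stat(f, "R", window, stat = sd)
  }, numeric(1))
  sd_curve <- data.frame(sigma = sigma_grid, sd_r = sd_rows)
  loglog <- coef(lm(log(sd_r) ~ log(sigma), data = sd_curve))[["log(sigma)"]]

  checks <- list(
    faster_when_certain = isTRUE(comparison$t_conv_upe[1] <
                                   comparison$t_conv_ctrl[1]),
    steadier_when_uncertain = isTRUE(comparison$sd_r_upe[2] <
                                       comparison$sd_r_ctrl[2]),
    sublinear_sd = isTRUE(loglog < 1))
  new_experiment("learning_rate_comparison",
                 list(sigma_low = sigma_low, sigma_high = sigma_high,
                      step_means = step_means,
                      samples_per_epoch = samples_per_epoch,
                      duration = duration, seed = seed, window = window),
                 list(comparison = comparison,
                      sd_curve = cbind(sd_curve, loglog_slope = loglog)),
                 checks)
}

#' Prior-sensory weighting sweep
#'
#' Runs the hierarchical circuit to steady state on a grid of sensory and
#' prior variances (PV activity clamped to the variances) for a set of
#' stimulus values, and compares the simulated representation against
#' the closed-form uncertainty-weighted average
#' [steady_state_representation()].  Also fits the representation-vs-
#' stimulus slope per grid cell: a slope below 1 is the contraction bias.
#'
#' @param sigma_s2_grid sensory variances; default
#'   `c(0.3, 0.5, 1, 1.5, 2)`.
#' @param sigma_p2_grid prior variances; same default.
#' @param prior prior mean; default 3.
#' @param s_values probe stimulus values; default `seq(1, 5, by = 1)`.
#' @param settle settling timesteps per probe; default 6000.
#' @inheritParams run_mean_learning
#' @return an `upe_experiment` with tables `grid` (per cell: maximum
#'   relative error vs the oracle and the fitted slope) and `points`
#'   (every simulated steady state).
#' @export
run_bayes_weighting_sweep <- function(sigma_s2_grid = c(0.3, 0.5, 1, 1.5, 2),
                                      sigma_p2_grid = c(0.3, 0.5, 1, 1.5, 2),
                                      prior = 3, s_values = seq(1, 5, 1),
                                      settle = 6000, seed = 0,
                                      params = upe_params()) {
  if (length(sigma_s2_grid) == 0L || length(sigma_p2_grid) == 0L)
    stop("invalid argument: empty grid")
  pts <- list(); cells <- list(); ii <- 0L
  for (ss in sigma_s2_grid) for (pp in sigma_p2_grid) {
    circuit <- upe_circuit("hierarchical", params,
                           clamp = list(sigma_s2 = ss, sigma_p2 = pp,
                                        prior = prior))
    r_sim <- vapply(s_values, function(sv) {
      sch <- upe_probe_schedule(sv, 0, duration = settle)
      f <- upe_train(circuit, sch, thin = settle)
      f$final$rates[["R"]]
    }, numeric(1))
    r_oracle <- steady_state_representation(s_values, prior, ss, pp)
    rel_err <- abs(r_sim - r_oracle) / pmax(abs(r_oracle), 1e-9)
    slope <- coef(lm(r_sim ~ s_values))[["s_values"]]
    ii <- ii + 1L
    pts[[ii]] <- data.frame(sigma_s2 = ss, sigma_p2 = pp, s = s_values,
                            r_sim = r_sim, r_oracle = r_oracle,
                            rel_err = rel_err)
    cells[[ii]] <- data.frame(sigma_s2 = ss, sigma_p2 = pp,
                              max_rel_err = max(rel_err), slope = slope)
  }
  grid <- do.call(rbind, cells)
  # slope should fall as sensory variance grows (at fixed prior variance)
  slope_monotone <- all(vapply(sigma_p2_grid, function(pp) {
    sl <- grid$slope[grid$sigma_p2 == pp][order(sigma_s2_grid)]
    all(diff(sl) < 0)
  }, logical(1)))
  checks <- list(
    oracle_match_2pct = max(grid$max_rel_err) <= 0.02,
    contraction_bias = all(grid$slope < 1),
    slope_falls_with_sensory_uncertainty = slope_monotone)
  new_experiment("bayes_weighting_sweep",
                 list(sigma_s2_grid = sigma_s2_grid,
                      sigma_p2_grid = sigma_p2_grid, prior = prior,
                      s_values = s_values, settle = settle, seed = seed),
                 list(grid = grid, points = do.call(rbind, pts)), checks)
}

#' Nudging-compensation sweep
#'
#' Trains the variance-learning circuit across a grid of nudging factors
#' beta, each with its compensation `ws = sqrt((2 - beta)/beta)`, and
#' reports the relative error of the converged cue-to-PV weight against
#' the true standard deviation.  The quadratic approximation behind the
#' compensation holds for small beta (up to about 0.2) and degrades
#' beyond it.
#'
#' @param beta_grid nudging factors in `(0, 1]`; default
#'   `c(0.05, 0.1, 0.2, 0.5, 0.8)`.
#' @param sigma trained standard deviation; default 0.8.
#' @param mu trained mean; default 5.
#' @param n_samples samples per condition; default 20000.
#' @inheritParams run_mean_learning
#' @return an `upe_experiment`; table `conditions` has per beta the
#'   converged weight and its relative error vs sigma.
#' @export
run_beta_compensation_sweep <- function(beta_grid = c(0.05, 0.1, 0.2, 0.5, 0.8),
                                        sigma = 0.8, mu = 5,
                                        n_samples = 20000, duration = 10,
                                        seed, window = 0.2) {
  if (missing(seed)) stop("'seed' is required")
  if (any(beta_grid <= 0 | beta_grid > 1))
    stop("invalid parameter: beta grid must lie in (0, 1]")
  rows <- lapply(seq_along(beta_grid), function(i) {
    b <- beta_grid[i]
    params <- upe_params(beta = b, ws = compensation_factor(b))
    sch <- upe_schedule(upe_context(mu, sigma), n_samples, duration,
                        seed = seed + i - 1L)
    fit <- upe_train(upe_circuit("pe+", params), sch)
    w <- coef(fit, window)[["w_pv_a"]]
    data.frame(beta = b, ws = params$ws, w_pv_a = w,
               rel_err = abs(w - sigma) / sigma)
  })
  tab <- do.call(rbind, rows)
  small <- tab$beta <= 0.2
  large <- tab$beta >= 0.5
  checks <- list(
    recovers_for_small_beta = all(tab$rel_err[small] <= 0.1),
    degrades_for_large_beta = !any(large) || all(tab$rel_err[large] > 0.1))
  new_experiment("beta_compensation_sweep",
                 list(beta_grid = beta_grid, sigma = sigma, mu = mu,
                      n_samples = n_samples, duration = duration,
                      seed = seed, window = window),
                 list(conditions = tab), checks)
}
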