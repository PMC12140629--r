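ff_rate_names <- function(variant)
  if (variant == "pe+") c("SST+", "PV+", "UPE+") else c("SST-", "PV-", "UPE-")

rec_rate_names <- c("SST+", "PV+", "UPE+", "SST-", "PV-", "UPE-", "R")
hier_rate_names <- c("UPEs+", "UPEs-", "UPEl+", "UPEl-", "R")

zero_weights <- function(circuit) {
  w0 <- rep(circuit$params$w_init, circuit$n_contexts)
  stats::setNames(lapply(circuit$plastic, function(nm) w0), circuit$plastic)
}

#' Train or simulate a microcircuit on a stimulus schedule
#'
#' Integrates the circuit's rate dynamics over the schedule with forward
#' Euler (time step `params$dt`), applying the local plasticity rules once
#' per timestep during training phases; probe and cue-only phases freeze
#' plasticity.  All stochasticity lives in the schedule, so identical
#' schedules give bit-identical fits.
#'
#' @param circuit an [upe_circuit()] object.
#' @param schedule an [upe_schedule()] (or step/probe/cue schedule).
#' @param thin record every `thin`-th timestep in the traces; default 10.
#'   Plasticity and dynamics always run at full resolution.
#' @param init optional initial state, as the `final` field of a previous
#'   fit (used by [simulate.upe_fit()] and [predict.upe_fit()]); default:
#'   all rates 0 and plastic weights at `params$w_init`.
#' @param learn_override optional logical scalar forcing plasticity on or
#'   off for the whole run, overriding the phase tags.
#' @return an object of class `upe_fit` with components `circuit`,
#'   `traces` (thinned data frame of rates, plastic weights, phase and
#'   context), `final` (exact end-state rates and weights), `schedule_meta`
#'   and `n_steps`.  Supports `coef`, `predict`, `simulate`, `residuals`,
#'   `fitted`, `plot`, `print`, `summary`.
#' @export
#' @examples
#' sch <- upe_schedule(upe_context(5, 0.4), n_samples = 200, seed = 1)
#' fit <- upe_train(upe_circuit("pe+"), sch)
#' coef(fit)
upe_train <- function(circuit, schedule, thin = 10L, init = NULL,
                      learn_override = NULL) {
  stopifnot(inherits(circuit, "upe_circuit"),
            inherits(schedule, "upe_schedule"))
  p <- circuit$params
  thin <- max(1L, as.integer(thin))
  n <- nrow(schedule)

  weights0 <- if (!is.null(init$weights)) init$weights else zero_weights(circuit)
  rate_names <- switch(circuit$variant,
                       "pe+" = , "pe-" = ff_rate_names(circuit$variant),
                       "recurrent" = rec_rate_names,
                       "hierarchical" = hier_rate_names)
  rates0 <- stats::setNames(rep(0, length(rate_names)), rate_names)
  if (!is.null(init$rates)) rates0[names(init$rates)] <- init$rates

  if (n == 0L) {
    traces <- cbind(data.frame(t = integer(0)),
                    as.data.frame(stats::setNames(
                      rep(list(numeric(0)), length(rate_names)), rate_names),
                      check.names = FALSE))
    return(new_upe_fit(circuit, schedule, traces, list(rates = rates0,
                                                       weights = weights0),
                       thin))
  }

  bad <- which(is.nan(schedule$s) | is.infinite(schedule$s))
  if (length(bad))
    stop("non-finite stimulus value at timestep ", bad[1L],
         " (use NA for an absent stimulus)")
  sig <- schedule_signals(schedule)
  if (any(sig$ctx < 1L | sig$ctx > circuit$n_contexts))
    stop("schedule context ids must lie in 1..n_contexts of the circuit")
  if (!is.null(learn_override)) sig$learn <- rep(isTRUE(learn_override), n)

  cpar <- par_for_cpp(p)
  if (circuit$variant %in% c("pe+", "pe-")) {
    negative <- circuit$variant == "pe-"
    r_pred <- if (negative) rep_len(as.numeric(circuit$clamp$prediction), n)
              else numeric(n)
    w_sst0 <- if (!is.null(weights0$w_sst_a)) weights0$w_sst_a
              else rep(0, circuit$n_contexts)
    res <- cpp_sim_ff(sig$ctx, sig$a, sig$s, sig$stim_on, sig$learn,
                      negative, r_pred, cpar, w_sst0, weights0$w_pv_a,
                      rates0, thin)
    wtr <- res$weights
    colnames(wtr) <- c("w_sst_a", "w_pv_a")
    if (negative) wtr <- wtr[, "w_pv_a", drop = FALSE]
    final_w <- if (negative) list(w_pv_a = res$w_pv_a)
               else list(w_sst_a = res$w_sst_a, w_pv_a = res$w_pv_a)
  } else if (circuit$variant == "recurrent") {
    clamp_r <- !is.null(circuit$clamp$representation)
    fixed_gain <- !is.null(circuit$clamp$gain)
    res <- cpp_sim_recurrent(sig$ctx, sig$a, sig$s, sig$stim_on, sig$learn,
                             cpar, weights0$w_r_a, weights0$w_pv_p_a,
                             weights0$w_pv_m_a, rates0, thin, fixed_gain,
                             if (fixed_gain) circuit$clamp$gain else 1.0,
                             clamp_r,
                             if (clamp_r) circuit$clamp$representation else 0.0)
    wtr <- res$weights
    colnames(wtr) <- c("w_r_a", "w_pv_p_a", "w_pv_m_a")
    final_w <- list(w_r_a = res$w_r_a, w_pv_p_a = res$w_pv_p_a,
                    w_pv_m_a = res$w_pv_m_a)
  } else {  # hierarchical (clamp mode, k = 1)
    if (anyNA(schedule$s))
      stop("hierarchical circuit needs a stimulus at every timestep")
    hpar <- cpar
    hpar$k <- 1.0
    res <- cpp_sim_hier(sig$s, circuit$clamp$prior, circuit$clamp$sigma_s2,
                        circuit$clamp$sigma_p2, hpar,
                        rates0[["R"]], thin)
    wtr <- NULL
    final_w <- list()
  }

  rmat <- res$rates
  colnames(rmat) <- rate_names
  traces <- data.frame(t = res$t)
  traces <- cbind(traces, as.data.frame(rmat, check.names = FALSE))
  if (!is.null(wtr)) traces <- cbind(traces, as.data.frame(wtr))
  traces$phase <- schedule$phase[res$t]
  traces$context_id <- schedule$context_id[res$t]

  final_r <- stats::setNames(as.numeric(res$r_final), rate_names)
  new_upe_fit(circuit, schedule, traces,
              list(rates = final_r, weights = final_w), thin)
}

new_upe_fit <- function(circuit, schedule, traces, final, thin) {
  structure(list(circuit = circuit, traces = traces, final = final,
                 thin = thin, n_steps = nrow(schedule),
                 schedule_meta = list(
                   contexts = attr(schedule, "contexts"),
                   duration = attr(schedule, "duration"),
                   seed = attr(schedule, "seed"),
                   phases = unique(schedule$phase))),
            class = "upe_fit")
}

# average of trace column `col` over the final `window` fraction of the
# training rows for one context
window_stat <- function(fit, col, window = 0.2, context = NULL,
                        stat = mean) {
  tr <- fit$traces
  keep <- startsWith(tr$phase, "train")
  if (!is.null(context)) keep <- keep & tr$context_id == context
  tr <- tr[keep, , drop = FALSE]
  if (nrow(tr) == 0L || is.null(tr[[col]])) return(NA_real_)
  tail_n <- max(1L, ceiling(window * nrow(tr)))
  stat(tr[[col]][(nrow(tr) - tail_n + 1L):nrow(tr)])
}

#' Converged plastic weights
#'
#' @param object an `upe_fit`.
#' @param window fraction of the training trace to average over (from the
#'   end); default 0.2.  `window = 0` returns the exact final weights.
#' @param ... unused.
#' @return named numeric vector of converged plastic weights; with more
#'   than one context channel, names gain a `[context]` suffix.
#' @export
coef.upe_fit <- function(object, window = 0.2, ...) {
  ws <- object$final$weights
  if (length(ws) == 0L) return(stats::setNames(numeric(0), character(0)))
  ctxs <- seq_len(object$circuit$n_contexts)
  out <- c()
  for (nm in names(ws)) {
    for (cc in ctxs) {
      val <- if (window > 0) window_stat(object, nm, window, context = cc)
             else NA_real_
      if (is.na(val)) val <- ws[[nm]][cc]
      key <- if (length(ctxs) > 1L) sprintf("%s[%d]", nm, cc) else nm
      out[key] <- val
    }
  }
  out
}

#' @export
print.upe_fit <- function(x, ...) {
  cat(sprintf("Trained '%s' circuit: %d timesteps (D = %s, seed = %s)\n",
              x$circuit$variant, x$n_steps,
              format(x$schedule_meta$duration),
              format(x$schedule_meta$seed)))
  cf <- coef(x)
  if (length(cf)) {
    cat("Converged weights (mean over final 20% of training):\n")
    print(round(cf, 4))
  }
  invisible(x)
}

#' @export
summary.upe_fit <- function(object, window = 0.2, ...) {
  cf <- coef(object, window)
  cf_sd <- vapply(names(object$final$weights), function(nm)
    window_stat(object, nm, window, stat = sd), numeric(1))
  rates <- vapply(
    setdiff(colnames(object$traces),
            c("t", "phase", "context_id", names(object$final$weights))),
    function(nm) window_stat(object, nm, window), numeric(1))
  structure(list(fit = object, coefficients = cf, coef_sd = cf_sd,
                 window = window, rates = rates),
            class = "summary.upe_fit")
}

#' @export
print.summary.upe_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Window-averaged rates (final %d%% of training):\n",
              round(100 * x$window)))
  print(round(x$rates, 4))
  invisible(x)
}

#' Learned readouts and probe responses
#'
#' `type = "readout"` presents the context cue alone (no stimulus, no
#' plasticity) until the rates settle and reports the learned predictions:
#' the mean carried by SST or R, and the variance carried by the PV rate.
#' `type = "response"` presents each stimulus in `newdata` as a frozen
#' probe from the trained state and reports steady-state rates of every
#' population — the mismatch-response readout.
#'
#' @param object an `upe_fit`.
#' @param newdata for `"response"`: numeric vector of probe stimulus
#'   values, or a data frame with column `s`.
#' @param type `"readout"` or `"response"`.
#' @param settle settling timesteps per probe; default
#'   `100 * tau_e / dt`.
#' @param freeze_representation for recurrent probes: clamp R at its
#'   trained value so error responses are read before the representation
#'   adapts; default `TRUE`.
#' @param context_id context channel to probe; default 1.
#' @param ... unused.
#' @return a data frame: one row per context (`"readout"`) or per probe
#'   stimulus (`"response"`).
#' @export
predict.upe_fit <- function(object, newdata = NULL,
                            type = c("readout", "response"), settle = NULL,
                            freeze_representation = TRUE, context_id = 1L,
                            ...) {
  type <- match.arg(type)
  p <- object$circuit$params
  if (is.null(settle)) settle <- ceiling(100 * p$tau_e / p$dt)

  if (type == "readout") {
    out <- lapply(seq_len(object$circuit$n_contexts), function(cc) {
      cue <- upe_cue_schedule(settle, context_id = cc)
      f <- upe_train(object$circuit, cue, thin = settle, init = object$final,
                     learn_override = FALSE)
      r <- f$final$rates
      w <- f$final$weights
      mu_hat <- if (!is.null(w$w_sst_a)) w$w_sst_a[cc]
                else if (!is.null(w$w_r_a)) w$w_r_a[cc] else NA_real_
      data.frame(context_id = cc, mu_hat = mu_hat,
                 sd_hat = if (!is.null(w$w_pv_a)) w$w_pv_a[cc]
                          else if (!is.null(w$w_pv_p_a)) w$w_pv_p_a[cc]
                          else NA_real_,
                 rate_mean = if ("SST+" %in% names(r)) r[["SST+"]]
                             else if ("R" %in% names(r)) r[["R"]] else NA_real_,
                 rate_var = if ("PV+" %in% names(r)) r[["PV+"]]
                            else if ("PV-" %in% names(r)) r[["PV-"]] else NA_real_)
    })
    return(do.call(rbind, out))
  }

  if (is.data.frame(newdata)) newdata <- newdata$s
  if (is.null(newdata)) stop("'newdata' (probe stimuli) required for response")
  circuit <- object$circuit
  if (circuit$variant == "recurrent" && isTRUE(freeze_representation)) {
    circuit$clamp$representation <- object$final$rates[["R"]]
  }
  out <- lapply(newdata, function(sv) {
    probe <- upe_probe_schedule(sv, 0, duration = settle,
                                context_id = context_id)
    f <- upe_train(circuit, probe, thin = settle, init = object$final,
                   learn_override = FALSE)
    cbind(data.frame(s = sv),
          as.data.frame(as.list(f$final$rates), check.names = FALSE))
  })
  do.call(rbind, out)
}

#' Continue a fitted circuit on a new schedule
#'
#' Runs further simulation from the trained state.  With
#' `plastic = FALSE` the weights are frozen regardless of phase tags.
#'
#' @param object an `upe_fit`.
#' @param nsim number of replicate continuations; default 1.
#' @param seed if `schedule` is `NULL`, a fresh training schedule with the
#'   fitted context table is drawn with this seed (required then).
#' @param schedule an `upe_schedule` to run; overrides `seed`.
#' @param plastic keep plasticity on during training phases; default TRUE.
#' @param thin trace thinning; default the fitted value.
#' @param ... unused.
#' @return an `upe_fit` (or a list of them when `nsim > 1`).
#' @export
simulate.upe_fit <- function(object, nsim = 1, seed = NULL, schedule = NULL,
                             plastic = TRUE, thin = NULL, ...) {
  if (is.null(thin)) thin <- object$thin
  one <- function(i) {
    sch <- schedule
    if (is.null(sch)) {
      if (is.null(seed)) stop("'seed' is required when no schedule is given")
      ctx <- object$schedule_meta$contexts
      if (anyNA(ctx$sigma)) stop("fitted schedule has no stimulus ",
                                 "distribution to redraw from")
      sch <- upe_schedule(ctx, n_samples = object$n_steps %/%
                            object$schedule_meta$duration %/% nrow(ctx),
                          duration = object$schedule_meta$duration,
                          seed = seed + i - 1L)
    }
    upe_train(object$circuit, sch, thin = thin, init = object$final,
              learn_override = if (plastic) NULL else FALSE)
  }
  if (nsim == 1L) one(1L) else lapply(seq_len(nsim), one)
}

#' @export
fitted.upe_fit <- function(object, ...) {
  tr <- object$traces
  switch(object$circuit$variant,
         "pe+" = tr[["SST+"]],
         "pe-" = rep_len(as.numeric(object$circuit$clamp$prediction),
                         nrow(tr)),
         tr[["R"]])
}

#' Signed uncertainty-modulated prediction error trace
#'
#' The difference of the positive and negative error populations over the
#' recorded trace (for the one-sided feedforward circuits, the single
#' error population with its sign).
#'
#' @param object an `upe_fit`.
#' @param ... unused.
#' @return numeric vector aligned with `object$traces$t`.
#' @export
residuals.upe_fit <- function(object, ...) {
  tr <- object$traces
  switch(object$circuit$variant,
         "pe+" = tr[["UPE+"]],
         "pe-" = -tr[["UPE-"]],
         "recurrent" = tr[["UPE+"]] - tr[["UPE-"]],
         "hierarchical" = tr[["UPEs+"]] - tr[["UPEs-"]])
}

#' Trace plots of a fitted circuit
#'
#' Two base-graphics panels: plastic weights over time and firing rates
#' over time.
#'
#' @param x an `upe_fit`.
#' @param which populations to show; default all recorded.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.upe_fit <- function(x, which = NULL, ...) {
  tr <- x$traces
  wcols <- intersect(names(x$final$weights), colnames(tr))
  rcols <- setdiff(colnames(tr), c("t", "phase", "context_id", wcols))
  if (!is.null(which)) rcols <- intersect(rcols, which)
  op <- graphics::par(mfrow = c(if (length(wcols)) 2 else 1, 1),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (length(wcols)) {
    graphics::matplot(tr$t, as.matrix(tr[, wcols, drop = FALSE]), type = "l",
                      lty = 1, xlab = "timestep", ylab = "weight",
                      main = "plastic weights", ...)
    graphics::legend("bottomright", legend = wcols, lty = 1,
                     col = seq_along(wcols), bty = "n")
  }
  graphics::matplot(tr$t, as.matrix(tr[, rcols, drop = FALSE]), type = "l",
                    lty = 1, xlab = "timestep", ylab = "rate",
                    main = "population rates", ...)
  graphics::legend("topright", legend = rcols, lty = 1,
                   col = seq_along(rcols), bty = "n")
  invisible(x)
}

#' Export a trace record as long-format CSV
#'
#' Columns `t, population, value`, one row per recorded rate or weight.
#'
#' @param fit an `upe_fit`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_trace <- function(fit, path) {
  tr <- fit$traces
  cols <- setdiff(colnames(tr), c("t", "phase", "context_id"))
  long <- do.call(rbind, lapply(cols, function(cc)
    data.frame(t = tr$t, population = cc, value = tr[[cc]])))
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
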