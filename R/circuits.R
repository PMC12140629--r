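#' Build a prediction-error microcircuit
#'
#' Assembles one of the four circuit variants:
#'
#' * `"pe+"` — feedforward positive prediction-error circuit: SST+ learns
#'   the mean from the cue, PV+ learns the standard deviation (its rate is
#'   the variance), UPE+ fires for stimuli above the prediction.
#'   Plastic weights: cue-to-SST and cue-to-PV.
#' * `"pe-"` — feedforward negative prediction-error circuit: SST- relays
#'   the stimulus, the mean prediction is a clamped input (`clamp$prediction`),
#'   UPE- fires for stimuli below the prediction.  Plastic: cue-to-PV.
#' * `"recurrent"` — both subcircuits wired to an internal representation
#'   neuron R, which learns the mean via the difference of UPE+ and UPE-.
#'   Plastic: cue-to-R and both cue-to-PV weights.
#' * `"hierarchical"` — two-area circuit: R integrates bottom-up UPEs
#'   (stimulus vs R, divided by the sensory variance) minus local UPEs
#'   (R vs prior, divided by the prior variance).  Run in clamp mode with
#'   `clamp = list(sigma_s2 =, sigma_p2 =, prior =)`; the PV clamp fixes
#'   the whole divisive denominator to the variance, and the dendritic
#'   exponent is 1 (the errors enter linearly), so the steady state is the
#'   variance-weighted average of stimulus and prior
#'   (see [steady_state_representation()]).
#'
#' @param variant one of `"pe+"`, `"pe-"`, `"recurrent"`, `"hierarchical"`.
#' @param params an [upe_params()] object.
#' @param n_contexts number of cue channels (each holds its own plastic
#'   weights); default 1.
#' @param clamp named list of clamped quantities: `prediction` (`"pe-"`),
#'   `representation` (optional, `"recurrent"`), `sigma_s2`, `sigma_p2`,
#'   `prior` (`"hierarchical"`).
#' @return an object of class `upe_circuit`.
#' @export
#' @examples
#' upe_circuit("pe+")
#' upe_circuit("pe-", clamp = list(prediction = 5))
upe_circuit <- function(variant = c("pe+", "pe-", "recurrent", "hierarchical"),
                        params = upe_params(), n_contexts = 1L,
                        clamp = list()) {
  variant <- match.arg(variant)
  if (!inherits(params, "upe_params"))
    stop("missing parameter: 'params' must be an upe_params object")
  n_contexts <- as.integer(n_contexts)
  stopifnot(n_contexts >= 1L)

  if (variant == "pe-" && is.null(clamp$prediction))
    stop("missing parameter: 'pe-' circuit needs clamp$prediction ",
         "(the mean prediction input)")
  if (variant == "hierarchical") {
    for (nm in c("sigma_s2", "sigma_p2", "prior"))
      if (is.null(clamp[[nm]]))
        stop("missing parameter: hierarchical circuit needs clamp$", nm)
    if (clamp$sigma_s2 <= 0 || clamp$sigma_p2 <= 0)
      stop("invalid parameter: clamped variances must be > 0")
  }

  populations <- switch(variant,
    "pe+" = c("SST+", "PV+", "UPE+"),
    "pe-" = c("SST-", "PV-", "UPE-"),
    "recurrent" = c("SST+", "PV+", "UPE+", "SST-", "PV-", "UPE-", "R"),
    "hierarchical" = c("UPEs+", "UPEs-", "UPEl+", "UPEl-", "R"))
  plastic <- switch(variant,
    "pe+" = c("w_sst_a", "w_pv_a"),
    "pe-" = "w_pv_a",
    "recurrent" = c("w_r_a", "w_pv_p_a", "w_pv_m_a"),
    "hierarchical" = character(0))

  structure(list(variant = variant, params = params,
                 n_contexts = n_contexts, clamp = clamp,
                 populations = populations, plastic = plastic),
            class = "upe_circuit")
}

#' @export
print.upe_circuit <- function(x, ...) {
  cat(sprintf("Prediction-error circuit ('%s'): populations %s\n",
              x$variant, paste(x$populations, collapse = ", ")))
  if (length(x$plastic))
    cat("  plastic:", paste(x$plastic, collapse = ", "),
        sprintf(" (%d context channel%s)\n", x$n_contexts,
                if (x$n_contexts > 1) "s" else ""))
  if (length(x$clamp))
    cat("  clamped:", paste(names(x$clamp), unlist(x$clamp), sep = " = ",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Uncertainty-weighted steady-state representation
#'
#' Closed-form fixed point of the hierarchical circuit: the
#' representation settles at the reliability-weighted average of the
#' sensory stimulus and the prior mean,
#' `r = (s/sigma_s2 + p/sigma_p2) / (1/sigma_s2 + 1/sigma_p2)`.
#' This is the oracle the simulated hierarchical circuit must match.
#'
#' @param s stimulus value(s).
#' @param p prior mean.
#' @param sigma_s2 sensory variance (> 0).
#' @param sigma_p2 prior variance (> 0).
#' @return the steady-state representation (vectorised over `s`).
#' @export
#' @examples
#' steady_state_representation(2, 1, 0.5, 1)   # 5/3
steady_state_representation <- function(s, p, sigma_s2, sigma_p2) {
  if (any(sigma_s2 <= 0) || any(sigma_p2 <= 0))
    stop("invalid parameter: variances must be > 0")
  (s / sigma_s2 + p / sigma_p2) / (1 / sigma_s2 + 1 / sigma_p2)
}

#' Maximum-likelihood mean update
#'
#' Reference comparator for what uncertainty-modulated errors
#' approximate: one stochastic-gradient step on the Gaussian
#' log-likelihood moves the mean estimate by
#' `eta * (s - mu_hat) / sigma2` — the prediction error scaled inversely
#' by the variance.
#'
#' @param s observed sample.
#' @param mu_hat current mean estimate.
#' @param sigma2 variance of the distribution (> 0).
#' @param eta learning rate; default 1.
#' @return the estimate increment.
#' @export
ml_mean_update <- function(s, mu_hat, sigma2, eta = 1) {
  if (any(sigma2 <= 0)) stop("invalid parameter: 'sigma2' must be > 0")
  eta * (s - mu_hat) / sigma2
}
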