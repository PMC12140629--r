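#' Circuit and plasticity parameters
#'
#' Collects every fixed weight, time constant and learning rate of the
#' microcircuit model, with defaults at the model's standard operating
#' point.  The compensation-bearing fixed weights (stimulus-to-PV and
#' SST-to-PV, and representation-to-PV in the negative circuit) are tied
#' to `ws = sqrt((2 - beta)/beta)` unless overridden explicitly.
#'
#' @param dt integration time step; default 0.1.
#' @param tau_e excitatory membrane time constant; default 1 (10 in
#'   mismatch-protocol runs).
#' @param tau_i inhibitory membrane time constant; default 1 (2 in
#'   mismatch-protocol runs).
#' @param beta nudging factor in `(0, 1]`; default 0.1.
#' @param ws compensation weight scale for the nudged PV pathway; default
#'   `compensation_factor(beta)`.
#' @param k dendritic exponent of the error neurons (`>= 1`); default 2.
#' @param I0 divisive offset (`>= 1` outside clamp mode so that division
#'   never amplifies); default 1.
#' @param xmax saturation input of the activation functions; default 20.
#' @param w_div weight of the divisive PV connection; default 1.
#' @param eta_sst learning rate of the cue-to-SST weight; default 0.1.
#' @param eta_pv learning rate of the cue-to-PV weight; default 0.001
#'   (`0.01 * eta_r`).
#' @param eta_r learning rate of the cue-to-representation weight;
#'   default 0.1 (0.01 in mismatch-protocol runs).
#' @param w_r_upe weight of the error inputs onto the representation
#'   neuron; default 0.1 (1.0 in mismatch-protocol runs).
#' @param r_gain integration gain of the representation neuron in the
#'   hierarchical circuit: the representation integrates the error
#'   difference `r_gain` times slower than the error populations relax,
#'   which keeps the multi-stage feedback loop overdamped at small
#'   variances without moving its fixed point; default 0.05.
#' @param w_init initial value of every plastic weight; default 0.01.
#' @param clip_weights clip plastic weights at zero after each update;
#'   default `FALSE` (they stay nonnegative in practice).
#' @return an object of class `upe_params` (a validated named list).
#' @export
#' @examples
#' p <- upe_params()
#' p$ws                      # sqrt(19) at beta = 0.1
#' upe_params(beta = 0.2)$ws # 3
upe_params <- function(dt = 0.1, tau_e = 1.0, tau_i = 1.0, beta = 0.1,
                       ws = compensation_factor(beta), k = 2, I0 = 1.0,
                       xmax = 20, w_div = 1.0, eta_sst = 0.1,
                       eta_pv = 0.001, eta_r = 0.1, w_r_upe = 0.1,
                       r_gain = 0.05, w_init = 0.01, clip_weights = FALSE) {
  p <- list(dt = dt, tau_e = tau_e, tau_i = tau_i, beta = beta, ws = ws,
            k = k, I0 = I0, xmax = xmax, w_div = w_div, eta_sst = eta_sst,
            eta_pv = eta_pv, eta_r = eta_r, w_r_upe = w_r_upe,
            r_gain = r_gain, w_init = w_init,
            clip_weights = isTRUE(clip_weights))
  validate_params(p)
  structure(p, class = "upe_params")
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk <- function(cond, msg) if (!cond) stop("invalid parameter: ", msg,
                                             call. = FALSE)
  chk(num1(p$dt) && p$dt > 0, "'dt' must be > 0")
  chk(num1(p$tau_e) && p$tau_e > 0, "'tau_e' must be > 0")
  chk(num1(p$tau_i) && p$tau_i > 0, "'tau_i' must be > 0")
  chk(num1(p$beta) && p$beta > 0 && p$beta <= 1, "'beta' must lie in (0, 1]")
  chk(num1(p$ws) && p$ws > 0, "'ws' must be > 0")
  chk(num1(p$k) && p$k >= 1, "'k' must be >= 1")
  chk(num1(p$I0) && p$I0 >= 1, "'I0' must be >= 1")
  chk(num1(p$xmax) && p$xmax > 0, "'xmax' must be > 0")
  chk(num1(p$w_div) && p$w_div >= 0, "'w_div' must be >= 0")
  for (nm in c("eta_sst", "eta_pv", "eta_r"))
    chk(num1(p[[nm]]) && p[[nm]] > 0, paste0("'", nm, "' must be > 0"))
  chk(num1(p$w_r_upe) && p$w_r_upe >= 0, "'w_r_upe' must be >= 0")
  chk(num1(p$r_gain) && p$r_gain > 0, "'r_gain' must be > 0")
  chk(num1(p$w_init), "'w_init' must be a finite number")
  invisible(p)
}

#' @export
print.upe_params <- function(x, ...) {
  cat("Microcircuit parameters\n")
  cat(sprintf("  dt = %g, tau_e = %g, tau_i = %g, xmax = %g\n",
              x$dt, x$tau_e, x$tau_i, x$xmax))
  cat(sprintf("  beta = %g (ws = %.4f), k = %g, I0 = %g, w_div = %g\n",
              x$beta, x$ws, x$k, x$I0, x$w_div))
  cat(sprintf("  eta_sst = %g, eta_pv = %g, eta_r = %g, w_r_upe = %g\n",
              x$eta_sst, x$eta_pv, x$eta_r, x$w_r_upe))
  cat(sprintf("  plastic weights start at %g%s\n", x$w_init,
              if (x$clip_weights) ", clipped at 0" else ""))
  invisible(x)
}

# parameter list handed to the compiled simulators
par_for_cpp <- function(p) {
  list(dt = p$dt, tau_e = p$tau_e, tau_i = p$tau_i, beta = p$beta,
       ws = p$ws, k = p$k, I0 = p$I0, xmax = p$xmax, w_div = p$w_div,
       eta_sst = p$eta_sst, eta_pv = p$eta_pv, eta_r = p$eta_r,
       w_r_upe = p$w_r_upe, r_gain = p$r_gain, clip_w = p$clip_weights)
}
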