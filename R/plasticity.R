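#' Local activity-dependent weight update
#'
#' The shared plasticity rule of all plastic afferents from the context
#' cue: `delta_w = eta * (r_post - phi(w * r_pre)) * r_pre`, with `phi`
#' the postsynaptic population's own transfer function (rectified-linear
#' for SST and the representation neuron, rectified-quadratic for PV).
#' Its fixed point makes the cue alone reproduce the average postsynaptic
#' rate, which is how the mean (SST) and the variance (PV) end up stored
#' in the cue weights.  Every term is available at the synapse: the rule
#' sees only the presynaptic rate, the postsynaptic rate and the local
#' dendritic prediction `phi(w * r_pre)`.
#'
#' @param w current weight.
#' @param r_pre presynaptic (cue) firing rate.
#' @param r_post postsynaptic firing rate.
#' @param eta learning rate (> 0).
#' @param kind postsynaptic transfer: `"linear"` (SST, R) or
#'   `"quadratic"` (PV).
#' @param xmax saturation input of the transfer.
#' @return the weight increment (not the updated weight).
#' @export
#' @examples
#' local_update(0, r_pre = 1, r_post = 3, eta = 0.1)   # 0.3
local_update <- function(w, r_pre, r_post, eta,
                         kind = c("linear", "quadratic"), xmax = 20) {
  kind <- match.arg(kind)
  if (!is.numeric(eta) || any(eta <= 0)) stop("'eta' must be positive")
  pred <- if (kind == "linear") phi(w * r_pre, xmax) else phi_pv(w * r_pre, xmax)
  eta * (r_post - pred) * r_pre
}

#' Nudging compensation factor
#'
#' Teaching inputs reach the interneurons scaled down by the nudging
#' factor `beta`, which shrinks the variance of the teaching signal.  For
#' the PV weight to converge to the stimulus standard deviation, the fixed
#' weights carrying the mean-subtracted stimulus must be scaled up by
#' `ws = sqrt((2 - beta) / beta)`.
#'
#' @param beta nudging factor, in `(0, 1]`.
#' @return the compensation weight scale `ws`.
#' @export
#' @examples
#' compensation_factor(1)    # 1
#' compensation_factor(0.2)  # 3
compensation_factor <- function(beta) {
  if (!is.numeric(beta) || any(beta <= 0) || any(beta > 1))
    stop("'beta' must lie in (0, 1]")
  sqrt((2 - beta) / beta)
}

#' Nudged input drive
#'
#' Convex combination of the learned feedforward drive and the teaching
#' drive: `(1 - beta) * feedforward + beta * target`.  During learning the
#' teaching signal (the stimulus, or the mean-subtracted stimulus) nudges
#' the interneuron towards its target activity.
#'
#' @param feedforward learned cue-driven input.
#' @param target teaching input.
#' @param beta nudging factor in `[0, 1]` (0 is allowed as the
#'   boundary used in tests; learning requires `beta > 0`).
#' @return the combined input current.
#' @export
nudged_drive <- function(feedforward, target, beta) {
  if (!is.numeric(beta) || any(beta < 0) || any(beta > 1))
    stop("'beta' must lie in [0, 1]")
  (1 - beta) * feedforward + beta * target
}

#' Balance-seeking inhibitory weight update
#'
#' Target-based rule that matches an inhibitory weight to the excitatory
#' current it must cancel: `delta_w = eta * r_pre_inh * (exc - inh)`.
#' Its fixed point is excitation-inhibition balance, the condition under
#' which error neurons are silent for perfectly predicted stimuli.
#'
#' @param w_inh current inhibitory weight (carried for interface
#'   symmetry; the increment does not depend on it directly, the
#'   inhibitory current does).
#' @param r_pre_inh presynaptic inhibitory firing rate (`>= 0`).
#' @param exc_current excitatory current to be matched.
#' @param inh_current current inhibitory current (`w_inh * r_pre_inh`).
#' @param eta learning rate (> 0).
#' @return the weight increment.
#' @export
#' @examples
#' balance_update(1, r_pre_inh = 1, exc_current = 2, inh_current = 1,
#'                eta = 0.1)   # 0.1
balance_update <- function(w_inh, r_pre_inh, exc_current, inh_current, eta) {
  if (!is.numeric(eta) || any(eta <= 0)) stop("'eta' must be positive")
  if (any(r_pre_inh < 0)) stop("rates must be nonnegative")
  eta * r_pre_inh * (exc_current - inh_current)
}
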