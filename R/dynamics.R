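#' Saturating rectified-linear activation
#'
#' Transfer function of SST, UPE and representation populations: zero below
#' threshold, the identity up to the saturation input `xmax`, and constant
#' at `rmax = xmax` beyond it.  `rmax` is tied to the activation value at
#' `xmax` so that saturation is continuous.
#'
#' @param x input current (any numeric vector).
#' @param xmax saturation input; activity is capped at `phi(xmax)`.
#' @return firing rate(s), same shape as `x`, in `[0, xmax]`.
#' @seealso [phi_pv()] for the quadratic PV transfer.
#' @export
#' @examples
#' phi(c(-1, 5, 25))
phi <- function(x, xmax = 20) {
  stopifnot(is.numeric(x), xmax > 0)
  pmin(pmax(x, 0), xmax)
}

#' Saturating rectified-quadratic activation
#'
#' Transfer function of PV interneurons: zero below threshold, `x^2` up to
#' the saturation input `xmax`, constant at `rmax = xmax^2` beyond.  The
#' supralinear integration is what lets the PV rate track a variance.
#'
#' @inheritParams phi
#' @return firing rate(s) in `[0, xmax^2]`.
#' @export
#' @examples
#' phi_pv(c(-2, 0.4, 0.8))
phi_pv <- function(x, xmax = 20) {
  stopifnot(is.numeric(x), xmax > 0)
  ifelse(x <= 0, 0, ifelse(x >= xmax, xmax^2, x^2))
}

#' Activation specification
#'
#' Small descriptor for a population's transfer function, used by
#' [euler_step()] and [local_update()].
#'
#' @param kind `"rectified-linear"` or `"rectified-quadratic"`.
#' @param xmax saturation input (> 0).
#' @return a list with fields `kind`, `xmax` and the implied `rmax`.
#' @export
activation_spec <- function(kind = c("rectified-linear", "rectified-quadratic"),
                            xmax = 20) {
  kind <- match.arg(kind)
  if (!is.numeric(xmax) || length(xmax) != 1L || xmax <= 0)
    stop("'xmax' must be a single positive number")
  structure(
    list(kind = kind, xmax = xmax,
         rmax = if (kind == "rectified-linear") xmax else xmax^2),
    class = "upe_activation")
}

apply_activation <- function(x, spec) {
  switch(spec$kind,
         "rectified-linear" = phi(x, spec$xmax),
         "rectified-quadratic" = phi_pv(x, spec$xmax))
}

#' Dendritic input current of an error neuron
#'
#' The apical comparison of excitation and subtractive inhibition,
#' rectified and raised to the dendritic exponent:
#' `max(exc - inh, 0)^k`.  With `k > 1` the dendrite amplifies large
#' prediction errors relative to small ones.
#'
#' @param exc excitatory drive (stimulus or representation input).
#' @param inh subtractive inhibitory drive (SST input).
#' @param k dendritic exponent, `k >= 1`; default 2.
#' @return dendritic current(s), nonnegative.
#' @export
#' @examples
#' dendritic_current(2, 1, k = 2)    # 1
#' dendritic_current(1, 2, k = 2)    # rectified to 0
#' dendritic_current(2, 0.5, k = 2.5)
dendritic_current <- function(exc, inh, k = 2) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("dendritic exponent 'k' must be a single number >= 1")
  pmax(exc - inh, 0)^k
}

#' Divisively modulated input of an error neuron
#'
#' Somatic input current after divisive PV inhibition:
#' `dend / (I0 + w_div * pv_rate)`.  The offset `I0` keeps the division
#' from ever amplifying when the learned variance is small.
#'
#' @param dend dendritic current (from [dendritic_current()]).
#' @param pv_rate divisive inhibitor (PV) firing rate, `>= 0`.
#' @param w_div weight of the divisive connection; default 1.
#' @param I0 divisive offset; default 1.
#' @return input current(s).
#' @export
#' @examples
#' upe_drive(1, pv_rate = 0.64)   # 1 / 1.64
upe_drive <- function(dend, pv_rate, w_div = 1, I0 = 1) {
  denom <- I0 + w_div * pv_rate
  if (any(denom <= 0))
    stop("divisive denominator I0 + w_div * pv_rate must be positive")
  dend / denom
}

#' One forward-Euler step of the leaky rate dynamics
#'
#' Advances every (unclamped) population by
#' `r <- r + dt/tau * (-r + phi(I))`, then clips rates to `[0, rmax]`.
#' This is the reference R implementation of the update that the compiled
#' simulators apply; it exists for inspection and for testing the
#' integration against the compiled path.
#'
#' @param rates named numeric vector of current firing rates.
#' @param inputs named numeric vector of total input currents (same names).
#' @param dt integration time step (> 0).
#' @param specs named list; per population a list with `tau` and an
#'   activation spec from [activation_spec()] (fields `kind`, `xmax`).
#' @return named numeric vector of updated rates.
#' @export
euler_step <- function(rates, inputs, dt, specs) {
  stopifnot(dt > 0)
  if (any(!is.finite(inputs))) {
    bad <- names(inputs)[!is.finite(inputs)]
    stop("non-finite input for population(s): ", paste(bad, collapse = ", "))
  }
  out <- rates
  for (nm in names(rates)) {
    sp <- specs[[nm]]
    target <- apply_activation(inputs[[nm]], sp$activation)
    r <- rates[[nm]] + dt / sp$tau * (-rates[[nm]] + target)
    out[[nm]] <- min(max(r, 0), sp$activation$rmax)
  }
  out
}
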