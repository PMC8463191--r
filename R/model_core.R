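#' Activation functions
#'
#' The sigmoid activation \code{Q(x) = 1/(1 + eps^(-x))} converts a mean
#' membrane potential into a firing rate in (0, 1); the steepness base
#' \code{eps} defaults to 250000, making Q a sharp but smooth switch with
#' \code{Q(0) = 0.5}.  The thalamic populations use the linear activation
#' \code{K(y) = a*y + b}, an affine approximation of the sigmoid valid in
#' the operating range of SRN and TRN (no clipping is applied).
#'
#' @param x,y mean membrane potential(s); must be finite.
#' @param eps_sigmoid sigmoid steepness base (> 1).
#' @param a,b slope and intercept of the linear activation.
#' @return numeric vector of activation values; \code{activation_sigmoid}
#'   is strictly increasing with range (0, 1).
#' @examples
#' activation_sigmoid(0)            # 0.5
#' activation_linear(0)             # 0.5
#' activation_sigmoid(0.5)          # ~0.998
#' @export
activation_sigmoid <- function(x, eps_sigmoid = 250000) {
  if (!all(is.finite(x))) stop("activation input must be finite")
  if (eps_sigmoid <= 1) stop("eps_sigmoid must exceed 1")
  k <- log(eps_sigmoid)
  stats::plogis(k * x)
}

#' @rdname activation_sigmoid
#' @export
activation_linear <- function(y, a = 2.8, b = 0.5) {
  if (!all(is.finite(y))) stop("activation input must be finite")
  a * y + b
}

#' Right-hand side of the coupled thalamocortical model
#'
#' Time derivative of the eight population potentials.  Within each module
#' the dynamics follow the Taylor-type cortico-thalamic circuit,
#' \deqn{dPY/dt = (\epsilon_{py} - PY + h_1 Q[PY] - h_2 Q[IN] + h_3 Q[SRN])\,\tau_1}
#' and analogously for IN, SRN, TRN, with the sigmoid activation Q on
#' cortical/relay inputs and the linear activation K on thalamic (SRN,
#' TRN) outputs.  The tau coefficients act as multiplicative rate
#' constants.  Cross-module terms use the same coupling strengths scaled
#' by \code{1/intermodule_scale} and sit outside the tau factor:
#' PY-PY (h1), IN-PY (h2), PY-IN (h4) between the two cortices, and
#' TRN-SRN (h6), SRN-TRN (h8), TRN-TRN (h9) between the two thalami.
#' Stimulation currents enter additively in the TRN equations only.
#'
#' This R implementation is the readable reference; the compiled
#' integrator used by \code{\link{ctmbc_simulate}} evaluates an identical
#' right-hand side.
#'
#' @param state numeric length 8 in the layout
#'   \code{(py1, in1, srn1, trn1, py2, in2, srn2, trn2)}
#'   (see \code{\link{population_state}}).
#' @param params a \code{\link{ctmbc_params}} object.
#' @param stim_trn1,stim_trn2 gated stimulation currents injected into
#'   TRN1 and TRN2 (already multiplied by their gates; 0 when no protocol
#'   is active).
#' @return named numeric vector of length 8: the time derivative.
#' @export
ctmbc_rhs <- function(state, params, stim_trn1 = 0, stim_trn2 = 0) {
  stopifnot(inherits(params, "ctmbc_params"), length(state) == 8)
  if (!all(is.finite(state)) || !is.finite(stim_trn1) ||
      !is.finite(stim_trn2)) {
    stop("state and stimulation inputs must be finite")
  }
  h <- params$h; eps <- params$eps; tau <- params$tau
  Q <- function(x) activation_sigmoid(x, params$eps_sigmoid)
  K <- function(y) activation_linear(y, params$a, params$b)
  cr <- 1 / params$intermodule_scale
  # gains of the cross input received by module I (g1) and module II (g2);
  # unidirectional drives the observed module I from an autonomous module II
  g1 <- if (params$topology %in% c("bidirectional", "unidirectional")) 1 else 0
  g2 <- if (params$topology == "bidirectional") 1 else 0
  xt <- if (params$cross_inside_tau) tau else rep(1, 4)

  py1 <- state[1]; in1 <- state[2]; srn1 <- state[3]; trn1 <- state[4]
  py2 <- state[5]; in2 <- state[6]; srn2 <- state[7]; trn2 <- state[8]

  d <- numeric(8)
  d[1] <- (eps[1] - py1 + h[1] * Q(py1) - h[2] * Q(in1) + h[3] * Q(srn1)) *
    tau[1] + g1 * xt[1] * cr * (h[1] * Q(py2) - h[2] * Q(in2))
  d[5] <- (eps[1] - py2 + h[1] * Q(py2) - h[2] * Q(in2) + h[3] * Q(srn2)) *
    tau[1] + g2 * xt[1] * cr * (h[1] * Q(py1) - h[2] * Q(in1))
  d[2] <- (eps[2] - in1 + h[4] * Q(py1)) * tau[2] +
    g1 * xt[2] * cr * h[4] * Q(py2)
  d[6] <- (eps[2] - in2 + h[4] * Q(py2)) * tau[2] +
    g2 * xt[2] * cr * h[4] * Q(py1)
  d[3] <- (eps[3] - srn1 + h[5] * Q(py1) - h[6] * K(trn1)) * tau[3] -
    g1 * xt[3] * cr * h[6] * K(trn2)
  d[7] <- (eps[3] - srn2 + h[5] * Q(py2) - h[6] * K(trn2)) * tau[3] -
    g2 * xt[3] * cr * h[6] * K(trn1)
  d[4] <- (eps[4] - trn1 + h[7] * Q(py1) + h[8] * K(srn1) - h[9] * K(trn1)) *
    tau[4] + g1 * xt[4] * cr * (h[8] * K(srn2) - h[9] * K(trn2)) + stim_trn1
  d[8] <- (eps[4] - trn2 + h[7] * Q(py2) + h[8] * K(srn2) - h[9] * K(trn2)) *
    tau[4] + g2 * xt[4] * cr * (h[8] * K(srn1) - h[9] * K(trn1)) + stim_trn2
  names(d) <- .state_names
  d
}
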