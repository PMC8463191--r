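#' Model parameters for the coupled thalamocortical model
#'
#' Builds the parameter set of the two-module, eight-population
#' thalamocortical neural mass model (a bidirectionally coupled pair of
#' Taylor-type cortico-thalamic circuits).  Each module contains an
#' excitatory pyramidal population (PY), an inhibitory interneuron
#' population (IN), the specific relay nucleus (SRN) and the thalamic
#' reticular nucleus (TRN).  The nine coupling strengths \code{h1..h9}
#' scale the intra-module projections; cross-module (long-range)
#' projections reuse the same strengths divided by
#' \code{intermodule_scale} (default 6).
#'
#' The time-scale coefficients \code{tau} are rate constants that multiply
#' the intra-module relaxation terms; cross-module terms enter outside the
#' tau factor (see \code{\link{ctmbc_rhs}}).  \code{h7} (PY to TRN) and
#' \code{h8} (SRN to TRN) are the free parameters swept in the state-map
#' analyses, with nominal ranges [1.5, 2.5] and [9, 11].
#'
#' @param h numeric length 9, coupling strengths; defaults
#'   \code{c(1.8, 1.5, 1, 4, 3, 0.6, 2, 10, 0.2)} with \code{h7}, \code{h8}
#'   at the midpoints of their sweep ranges.
#' @param h7,h8 optional scalar overrides for \code{h[7]} and \code{h[8]}.
#' @param eps constant population inputs for (PY, IN, SRN, TRN); default
#'   \code{c(-0.35, -3.4, -2, -5)}.
#' @param tau time-scale coefficients (rate constants, 1/s on the physical
#'   time axis); default \code{c(26, 32.5, 2.6, 2.6)}.
#' @param a,b slope and intercept of the linear thalamic activation
#'   \code{K(y) = a*y + b}; defaults 2.8 and 0.5.
#' @param eps_sigmoid steepness base of the sigmoid activation
#'   \code{Q(x) = 1/(1 + eps_sigmoid^(-x))}; default 250000.
#' @param intermodule_scale divisor applied to \code{h_i} for cross-module
#'   terms; default 6 (long-range transmission), 3 selects the short-range
#'   variant.
#' @param topology one of \code{"bidirectional"} (both modules receive
#'   cross input), \code{"unidirectional"} (the analysed module I receives
#'   cross input from an autonomous module II) or \code{"uncoupled"} (no
#'   cross terms).
#' @param cross_inside_tau logical; when \code{TRUE} the cross-module terms
#'   are multiplied by the same tau factor as the intra-module bracket.
#'   Off by default; provided for sensitivity checks only.
#' @return an object of class \code{"ctmbc_params"}.
#' @examples
#' p <- ctmbc_params(h7 = 2.5, h8 = 9.2)
#' p
#' @export
ctmbc_params <- function(h = c(1.8, 1.5, 1, 4, 3, 0.6, 2, 10, 0.2),
                         h7 = NULL, h8 = NULL,
                         eps = c(-0.35, -3.4, -2, -5),
                         tau = c(26, 32.5, 2.6, 2.6),
                         a = 2.8, b = 0.5,
                         eps_sigmoid = 250000,
                         intermodule_scale = 6,
                         topology = c("bidirectional", "unidirectional",
                                      "uncoupled"),
                         cross_inside_tau = FALSE) {
  topology <- match.arg(topology)
  stopifnot(length(h) == 9, length(eps) == 4, length(tau) == 4,
            is.finite(h), is.finite(eps), is.finite(tau),
            is.finite(a), is.finite(b))
  if (!is.null(h7)) h[7] <- h7
  if (!is.null(h8)) h[8] <- h8
  if (any(tau <= 0)) stop("tau coefficients must be positive")
  if (eps_sigmoid <= 1) stop("eps_sigmoid must exceed 1")
  if (intermodule_scale <= 0) stop("intermodule_scale must be positive")
  p <- list(h = as.numeric(h), eps = as.numeric(eps), tau = as.numeric(tau),
            a = a, b = b, eps_sigmoid = eps_sigmoid,
            intermodule_scale = intermodule_scale,
            topology = topology,
            cross_inside_tau = isTRUE(cross_inside_tau))
  class(p) <- "ctmbc_params"
  p
}

#' @export
print.ctmbc_params <- function(x, ...) {
  cat("Coupled thalamocortical model parameters\n")
  cat("  h1..h9:", paste(format(x$h), collapse = " "), "\n")
  cat("  eps (PY, IN, SRN, TRN):", paste(format(x$eps), collapse = " "), "\n")
  cat("  tau:", paste(format(x$tau), collapse = " "),
      " a:", x$a, " b:", x$b, " sigmoid base:", format(x$eps_sigmoid), "\n")
  cat("  topology:", x$topology,
      " cross-module scale: h/", format(x$intermodule_scale), "\n", sep = "")
  invisible(x)
}

# internal: list passed to the compiled integrator
pars_for_cpp <- function(params) {
  stopifnot(inherits(params, "ctmbc_params"))
  code <- match(params$topology,
                c("bidirectional", "unidirectional", "uncoupled")) - 1L
  list(h = params$h, eps = params$eps, tau = params$tau,
       a = params$a, b = params$b, eps_sigmoid = params$eps_sigmoid,
       intermodule_scale = params$intermodule_scale,
       topology_code = code,
       cross_inside_tau = params$cross_inside_tau)
}

#' Population state vector
#'
#' Constructs the 8-component state vector of the model in the fixed
#' layout \code{(py1, in1, srn1, trn1, py2, in2, srn2, trn2)}.  This
#' ordering is part of the public contract: every trajectory matrix
#' returned by the package uses these column names in this order.
#'
#' @param py1,in1,srn1,trn1 module-I mean membrane potentials.
#' @param py2,in2,srn2,trn2 module-II mean membrane potentials.
#' @return named numeric vector of length 8.
#' @export
population_state <- function(py1 = 0, in1 = 0, srn1 = 0, trn1 = 0,
                             py2 = 0, in2 = 0, srn2 = 0, trn2 = 0) {
  x <- c(py1 = py1, in1 = in1, srn1 = srn1, trn1 = trn1,
         py2 = py2, in2 = in2, srn2 = srn2, trn2 = trn2)
  if (!all(is.finite(x))) stop("population state must be finite")
  x
}

.state_names <- c("py1", "in1", "srn1", "trn1", "py2", "in2", "srn2", "trn2")

#' Read or write a flat key-value parameter profile
#'
#' Parameter sets are serialized as a plain-text Debian-control-style
#' (key: value) document, human-editable and round-trip safe.  A bundled
#' profile reproducing the default (published) parameter set ships with
#' the package:
#' \code{read_ctmbc_config(system.file("extdata", "defaults.cfg",
#' package = "ctmbc"))}.
#'
#' @param params a \code{ctmbc_params} object.
#' @param path file path.
#' @return \code{read_ctmbc_config} returns a \code{ctmbc_params} object.
#' @export
write_ctmbc_config <- function(params, path) {
  stopifnot(inherits(params, "ctmbc_params"))
  df <- data.frame(
    h = paste(format(params$h, digits = 15), collapse = " "),
    eps = paste(format(params$eps, digits = 15), collapse = " "),
    tau = paste(format(params$tau, digits = 15), collapse = " "),
    a = format(params$a, digits = 15),
    b = format(params$b, digits = 15),
    eps_sigmoid = format(params$eps_sigmoid, digits = 15),
    intermodule_scale = format(params$intermodule_scale, digits = 15),
    topology = params$topology,
    cross_inside_tau = params$cross_inside_tau)
  write.dcf(df, file = path)
  invisible(path)
}

#' @rdname write_ctmbc_config
#' @export
read_ctmbc_config <- function(path) {
  m <- read.dcf(path)
  num <- function(key) as.numeric(strsplit(m[1, key], "[[:space:]]+")[[1]])
  ctmbc_params(h = num("h"), eps = num("eps"), tau = num("tau"),
               a = num("a"), b = num("b"),
               eps_sigmoid = num("eps_sigmoid"),
               intermodule_scale = num("intermodule_scale"),
               topology = m[1, "topology"],
               cross_inside_tau = identical(m[1, "cross_inside_tau"], "TRUE"))
}
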