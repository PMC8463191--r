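#' Stimulation protocols
#'
#' Defines the four therapy waveform families applied to the thalamic
#' reticular nuclei:
#' \describe{
#'   \item{\code{"none"}}{no stimulation (baseline).}
#'   \item{\code{"dbs"}}{deep brain stimulation: a periodic rectangular
#'     pulse train of amplitude \code{amplitude}, period \code{1/frequency}
#'     and pulse width \code{pulse_width}, applied to both TRN populations
#'     simultaneously.}
#'   \item{\code{"cbbp"}}{charge-balanced biphasic pulse: per period an
#'     anodic phase of amplitude \code{+amplitude} for \code{pulse_width}
#'     seconds followed by a cathodic phase whose amplitude
#'     \code{-amplitude*delta/(T-delta)} makes the net charge per period
#'     exactly zero; applied to both TRN populations.}
#'   \item{\code{"crs"}}{coordinated reset: the DBS pulse train gated by an
#'     \code{m:n} ON-OFF schedule that alternates between TRN1 and TRN2
#'     (starting with TRN1); \code{m} ON cycles are followed by \code{n}
#'     OFF cycles.  \code{crs = c(1, 0)} is perpetual alternation,
#'     \code{crs = c(3, 2)} stimulates for three cycles and pauses for
#'     two.}
#' }
#'
#' The amplitude is signed: negative values are cathodic
#' (hyperpolarizing) currents.  The default is -3 (mA-equivalent model
#' units): therapeutic stimulation of the reticular nucleus acts in this
#' model by suppressing TRN activation, which requires a hyperpolarizing
#' pulse; cathodic pulses of magnitude 3 reproduce the published
#' suppression maps (see the methods vignette for the polarity
#' discussion).  Frequency defaults to 130 Hz and pulse width to 4 ms.
#'
#' @param kind waveform family.
#' @param amplitude signed pulse amplitude (mA-equivalent model units);
#'   negative = cathodic.
#' @param frequency pulse repetition rate (Hz); the period is
#'   \code{1/frequency} s.
#' @param pulse_width pulse duration (s); must be shorter than the period.
#' @param crs integer pair \code{c(m, n)}: ON and OFF cycle counts
#'   (\code{m >= 1}, \code{n >= 0}); only used when \code{kind = "crs"}.
#' @param crs_cycle duration of one CRS cycle (s); defaults to one
#'   stimulus period so each ON cycle delivers one pulse.
#' @param cbbp_period period of the biphasic waveform (s); defaults to
#'   \code{1/frequency}.
#' @param cbbp_literal logical; reproduce the printed biphasic form whose
#'   anodic amplitude equals \code{pulse_width} numerically instead of the
#'   charge-balanced \code{amplitude}.  Off by default.
#' @return an object of class \code{"ctmbc_protocol"}.
#' @examples
#' stim_protocol("dbs", amplitude = 2)
#' stim_protocol("crs", crs = c(3, 2))
#' @export
stim_protocol <- function(kind = c("none", "dbs", "cbbp", "crs"),
                          amplitude = -3, frequency = 130,
                          pulse_width = 0.004,
                          crs = c(1, 0), crs_cycle = NULL,
                          cbbp_period = NULL, cbbp_literal = FALSE) {
  kind <- match.arg(kind)
  period <- 1 / frequency
  if (is.null(cbbp_period)) cbbp_period <- period
  if (is.null(crs_cycle)) crs_cycle <- period
  if (kind == "dbs" && pulse_width >= period) {
    stop("pulse_width must be shorter than the stimulation period")
  }
  if (kind == "cbbp" && (pulse_width <= 0 || pulse_width >= cbbp_period)) {
    stop("pulse_width must lie strictly inside the biphasic period")
  }
  if (kind == "crs") {
    if (length(crs) != 2 || crs[1] < 1 || crs[2] < 0 ||
        any(crs != round(crs))) {
      stop("crs must be integer c(m, n) with m >= 1, n >= 0")
    }
    if (crs_cycle <= 0) stop("crs_cycle must be positive")
  }
  p <- list(kind = kind, amplitude = amplitude, frequency = frequency,
            period = period, pulse_width = pulse_width,
            crs_m = as.integer(crs[1]), crs_n = as.integer(crs[2]),
            crs_cycle = crs_cycle, cbbp_period = cbbp_period,
            cbbp_literal = isTRUE(cbbp_literal))
  class(p) <- "ctmbc_protocol"
  p
}

#' @rdname stim_protocol
#' @export
stim_none <- function() stim_protocol("none")

#' @export
print.ctmbc_protocol <- function(x, ...) {
  if (x$kind == "none") {
    cat("Stimulation protocol: none\n")
    return(invisible(x))
  }
  cat("Stimulation protocol:", toupper(x$kind))
  if (x$kind == "crs") cat(sprintf(" %d:%d", x$crs_m, x$crs_n))
  cat(sprintf("\n  amplitude %g, frequency %g Hz, pulse width %g ms\n",
              x$amplitude, x$frequency, 1000 * x$pulse_width))
  if (x$kind == "crs") {
    cat(sprintf("  cycle length %g ms, alternating targets starting at TRN1\n",
                1000 * x$crs_cycle))
  }
  invisible(x)
}

# internal: list passed to the compiled integrator
stim_for_cpp <- function(protocol) {
  stopifnot(inherits(protocol, "ctmbc_protocol"))
  code <- match(protocol$kind, c("none", "dbs", "cbbp", "crs")) - 1L
  list(kind_code = code, amplitude = protocol$amplitude,
       period = protocol$period, pulse_width = protocol$pulse_width,
       cbbp_period = protocol$cbbp_period,
       crs_m = protocol$crs_m, crs_n = protocol$crs_n,
       crs_cycle = protocol$crs_cycle,
       cbbp_literal = protocol$cbbp_literal)
}

#' Stimulation waveforms and gates
#'
#' \code{dbs_waveform} evaluates the rectangular pulse train: the pulse
#' occupies the first \code{pulse_width} seconds of each period (the pulse
#' begins at each period start).  \code{cbbp_waveform} evaluates the
#' charge-balanced biphasic waveform.  \code{crs_gates} returns the binary
#' gate pair (beta1, beta2) of the coordinated-reset schedule; the gates
#' are mutually exclusive and depend only on the cycle index.
#' \code{stim_currents} combines waveform and gates into the pair of gated
#' currents actually injected into TRN1 and TRN2 for any protocol kind.
#'
#' @param t time(s) in seconds, \code{t >= 0}; vectorized.
#' @param protocol a \code{\link{stim_protocol}} object of the matching
#'   kind.
#' @return \code{dbs_waveform} and \code{cbbp_waveform}: numeric vector of
#'   currents.  \code{crs_gates}: two-column 0/1 matrix \code{beta1},
#'   \code{beta2}.  \code{stim_currents}: two-column matrix of gated
#'   currents \code{trn1}, \code{trn2}.
#' @examples
#' p <- stim_protocol("dbs", amplitude = 2, frequency = 130)
#' dbs_waveform(c(0.001, 0.006), p)    # 2, 0
#' @export
dbs_waveform <- function(t, protocol) {
  stopifnot(inherits(protocol, "ctmbc_protocol"))
  if (protocol$kind == "none") return(rep(0, length(t)))
  if (any(t < 0)) stop("t must be non-negative")
  rho <- protocol$period
  phase <- period_phase(t, rho)
  ifelse(phase < protocol$pulse_width - 1e-9 * rho, protocol$amplitude, 0)
}

# phase inside one period with the same boundary tie-break as the compiled
# integrator: boundary times count as phase 0, the pulse is [0, delta)
period_phase <- function(t, P) {
  phase <- t - P * floor(t / P)
  phase[P - phase < 1e-9 * P] <- 0
  phase
}

#' @rdname dbs_waveform
#' @export
cbbp_waveform <- function(t, protocol) {
  stopifnot(inherits(protocol, "ctmbc_protocol"),
            protocol$kind %in% c("cbbp"))
  if (any(t < 0)) stop("t must be non-negative")
  Tp <- protocol$cbbp_period
  delta <- protocol$pulse_width
  if (protocol$cbbp_literal) {
    # printed form: amplitudes (delta, -delta/(T-delta)); not balanced
    ap <- delta
    cp <- -delta / (Tp - delta)
  } else {
    ap <- protocol$amplitude
    cp <- -protocol$amplitude * delta / (Tp - delta)
  }
  phase <- period_phase(t, Tp)
  ifelse(phase < delta - 1e-9 * Tp, ap, cp)
}

#' @rdname dbs_waveform
#' @export
crs_gates <- function(t, protocol) {
  stopifnot(inherits(protocol, "ctmbc_protocol"), protocol$kind == "crs")
  if (any(t < 0)) stop("t must be non-negative")
  cyc <- floor(t / protocol$crs_cycle + 1e-9)
  sp <- protocol$crs_m + protocol$crs_n
  pos <- cyc %% sp
  on <- pos < protocol$crs_m
  on_idx <- (cyc %/% sp) * protocol$crs_m + pos
  beta1 <- as.numeric(on & on_idx %% 2 == 0)
  beta2 <- as.numeric(on & on_idx %% 2 == 1)
  cbind(beta1 = beta1, beta2 = beta2)
}

#' @rdname dbs_waveform
#' @export
stim_currents <- function(t, protocol) {
  stopifnot(inherits(protocol, "ctmbc_protocol"))
  out <- switch(protocol$kind,
    none = cbind(trn1 = rep(0, length(t)), trn2 = rep(0, length(t))),
    dbs = {
      u <- dbs_waveform(t, protocol)
      cbind(trn1 = u, trn2 = u)
    },
    cbbp = {
      u <- cbbp_waveform(t, protocol)
      cbind(trn1 = u, trn2 = u)
    },
    crs = {
      u <- dbs_waveform(t, protocol)
      g <- crs_gates(t, protocol)
      cbind(trn1 = g[, 1] * u, trn2 = g[, 2] * u)
    })
  out
}

#' Root-mean-square current
#'
#' Standard RMS of a sampled current trace,
#' \code{sqrt(mean(u^2))}: the energy-expenditure metric used to compare
#' stimulation schemes.
#'
#' @param samples numeric vector of current samples (at least one).
#' @return scalar RMS value.
#' @examples
#' rms_current(rep(2, 10))   # 2
#' @export
rms_current <- function(samples) {
  if (length(samples) < 1) stop("rms_current needs at least one sample")
  if (!all(is.finite(samples))) stop("samples must be finite")
  sqrt(mean(samples^2))
}

#' Export a waveform as a two-column text table
#'
#' Writes (time, current) pairs as CSV for external inspection.
#'
#' @param protocol a \code{\link{stim_protocol}} object.
#' @param path output file path.
#' @param t time grid (s); default covers 0.1 s at 0.1 ms resolution.
#' @export
write_waveform <- function(protocol, path,
                           t = seq(0, 0.1, by = 1e-4)) {
  cur <- stim_currents(t, protocol)
  utils::write.csv(data.frame(time = t, trn1 = cur[, 1], trn2 = cur[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}
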