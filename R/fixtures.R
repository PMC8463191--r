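#' Synthetic classifier-test traces
#'
#' Analytic waveforms with known labels and dominant frequencies, used to
#' exercise the state classifier independently of the model: a pure sine
#' (simple oscillation), a two-bump spike-wave composite (fundamental
#' plus strong second harmonic, two prominent maxima per period),
#' constant high/low traces (saturated and low-firing fixed points), a
#' fast sine outside the 2-4 Hz band, and a two-tone mixture whose
#' dominant peak is the low-frequency component.
#'
#' @param seed seed for the small phase jitter applied to the composite
#'   (keeps the fixture from being perfectly grid-aligned).
#' @param sample_rate sampling rate (Hz).
#' @param duration trace length (s).
#' @return named list; each element has \code{trace}, \code{label} (the
#'   expected classification) and \code{frequency} (expected dominant
#'   frequency, Hz).
#' @export
synthetic_traces <- function(seed = 1, sample_rate = 500, duration = 20) {
  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(rng_state))
      assign(".Random.seed", rng_state, envir = globalenv())
  })
  set.seed(seed)
  t <- seq(0, duration, by = 1 / sample_rate)
  phi <- stats::runif(1, 0, 2 * pi)
  list(
    sine_3hz = list(
      trace = 0.3 * sin(2 * pi * 3 * t + phi) + 0.3,
      label = "II", frequency = 3),
    swd_3hz = list(
      # spike (strong 2nd harmonic) riding on a 3 Hz wave: two prominent
      # maxima per fundamental period
      trace = 0.25 * (sin(2 * pi * 3 * t + phi) +
                        0.95 * sin(2 * pi * 6 * t + 2 * phi)) + 0.3,
      label = "III", frequency = 3),
    constant_high = list(
      trace = rep(0.46, length(t)), label = "I", frequency = 0),
    constant_low = list(
      trace = rep(0.16, length(t)), label = "IV", frequency = 0),
    sine_8hz = list(
      trace = 0.3 * sin(2 * pi * 8 * t + phi), label = "II", frequency = 8),
    two_tone = list(
      # frequency fixture only: the dominant peak is the stronger low tone
      trace = 2 * sin(2 * pi * 2.5 * t + phi) + sin(2 * pi * 8 * t),
      label = NA_character_, frequency = 2.5))
}
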