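#' Simulation configuration
#'
#' Integration settings for the fixed-step fourth-order Runge-Kutta
#' solver.  Defaults follow the published protocol: 30 s of simulated
#' time at a 0.25 ms step, with the first 10 s discarded as transient and
#' 20 independent repeats from random initial conditions.
#'
#' @param dt integration step (s).
#' @param duration total simulated time (s).
#' @param transient leading interval discarded for all statistics (s).
#' @param n_repeats number of independent runs in an ensemble.
#' @param seed integer seed for the initial-condition RNG.
#' @param init_range bounds of the uniform initial-condition distribution
#'   applied independently to each of the 8 components.
#' @param record_every record every k-th integration step (thin the
#'   stored trajectory; the integrator always steps at \code{dt}).
#' @param overflow_guard absolute state bound beyond which a run is
#'   flagged divergent (the run is truncated, not an error).
#' @return an object of class \code{"ctmbc_config"}.
#' @export
sim_config <- function(dt = 0.25e-3, duration = 30, transient = 10,
                       n_repeats = 20, seed = 1,
                       init_range = c(-1, 1), record_every = 1L,
                       overflow_guard = 1e6) {
  stopifnot(dt > 0, dt < duration, transient >= 0, transient < duration,
            n_repeats >= 1, length(init_range) == 2,
            init_range[1] < init_range[2], record_every >= 1)
  cfg <- list(dt = dt, duration = duration, transient = transient,
              n_repeats = as.integer(n_repeats), seed = as.integer(seed),
              init_range = init_range,
              record_every = as.integer(record_every),
              overflow_guard = overflow_guard)
  class(cfg) <- "ctmbc_config"
  cfg
}

#' Integrate the coupled thalamocortical model
#'
#' Classic fixed-step RK4 with the stimulation current evaluated
#' analytically at every sub-step time (t, t + dt/2, t + dt).  The gated
#' currents enter the two TRN equations only.  Integration is fully
#' deterministic given the initial state.  If any component exceeds the
#' overflow guard the run is truncated and flagged divergent rather than
#' raising an error, so parameter sweeps survive divergent corners.
#'
#' @param params a \code{\link{ctmbc_params}} object.
#' @param protocol a \code{\link{stim_protocol}} object.
#' @param config a \code{\link{sim_config}} object.
#' @param initial numeric length 8 initial state; when \code{NULL} a
#'   single state is drawn uniformly from \code{config$init_range} using
#'   \code{config$seed}.
#' @return an object of class \code{"ctmbc_sim"} with elements
#'   \code{time} (s), \code{states} (matrix, one column per population),
#'   \code{stim1}/\code{stim2} (gated currents injected into TRN1/TRN2 on
#'   the recorded grid), \code{mean_field} (0.5*(PY1+IN1)),
#'   \code{mean_field2} (0.5*(PY2+IN2)), \code{sample_rate} (Hz),
#'   \code{diverged}, \code{diverge_time}, and the generating
#'   \code{params}, \code{protocol}, \code{config}, \code{initial}.
#' @examples
#' \donttest{
#' p <- ctmbc_params(h7 = 2.5, h8 = 9.2)
#' s <- ctmbc_simulate(p, config = sim_config(duration = 15, transient = 5))
#' summary(s)
#' }
#' @export
ctmbc_simulate <- function(params, protocol = stim_none(),
                           config = sim_config(), initial = NULL) {
  stopifnot(inherits(params, "ctmbc_params"),
            inherits(protocol, "ctmbc_protocol"),
            inherits(config, "ctmbc_config"))
  if (is.null(initial)) {
    initial <- draw_initials(1, config)[1, ]
  }
  if (length(initial) != 8 || !all(is.finite(initial))) {
    stop("initial state must be 8 finite values")
  }
  n_steps <- as.integer(round(config$duration / config$dt))
  raw <- .rk4_integrate(as.numeric(initial), pars_for_cpp(params),
                        stim_for_cpp(protocol), config$dt, n_steps,
                        config$record_every, config$overflow_guard)
  colnames(raw$states) <- .state_names
  out <- list(time = raw$time, states = raw$states,
              stim1 = raw$stim1, stim2 = raw$stim2,
              mean_field = 0.5 * (raw$states[, "py1"] + raw$states[, "in1"]),
              mean_field2 = 0.5 * (raw$states[, "py2"] + raw$states[, "in2"]),
              sample_rate = 1 / (config$dt * config$record_every),
              diverged = raw$diverged, diverge_time = raw$diverge_time,
              params = params, protocol = protocol, config = config,
              initial = as.numeric(initial))
  class(out) <- "ctmbc_sim"
  out
}

# uniform initial conditions, one row per repeat, from the config seed
draw_initials <- function(n, config) {
  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(rng_state))
      assign(".Random.seed", rng_state, envir = globalenv())
  })
  set.seed(config$seed)
  matrix(stats::runif(n * 8, config$init_range[1], config$init_range[2]),
         nrow = n, ncol = 8, byrow = TRUE,
         dimnames = list(NULL, .state_names))
}

#' Run an ensemble of independent simulations
#'
#' Performs \code{config$n_repeats} integrations whose initial states are
#' drawn uniformly from \code{config$init_range} by a RNG seeded with
#' \code{config$seed}; the draw is a single deterministic block, so the
#' whole ensemble is reproduced bit-for-bit from (params, protocol,
#' config).  Raw trajectories are returned per run; categorical labels
#' and spectral statistics are combined downstream
#' (\code{\link{sweep_2d}}), not the trajectories themselves.
#'
#' @inheritParams ctmbc_simulate
#' @return an object of class \code{"ctmbc_ensemble"}: a list of
#'   \code{ctmbc_sim} objects with the shared configuration attached.
#' @export
run_ensemble <- function(params, protocol = stim_none(),
                         config = sim_config()) {
  inits <- draw_initials(config$n_repeats, config)
  runs <- lapply(seq_len(config$n_repeats), function(i) {
    ctmbc_simulate(params, protocol, config, initial = inits[i, ])
  })
  structure(list(runs = runs, params = params, protocol = protocol,
                 config = config),
            class = "ctmbc_ensemble")
}

#' @export
print.ctmbc_sim <- function(x, ...) {
  cat(sprintf("Thalamocortical simulation: %.3g s at dt = %g ms (%d samples)\n",
              max(x$time), 1000 * x$config$dt * x$config$record_every,
              length(x$time)))
  cat("  topology:", x$params$topology,
      sprintf(" h7 = %g, h8 = %g", x$params$h[7], x$params$h[8]), "\n")
  cat("  protocol:", x$protocol$kind, "\n")
  if (x$diverged) {
    cat(sprintf("  DIVERGED at t = %.3f s\n", x$diverge_time))
  }
  invisible(x)
}

#' @export
summary.ctmbc_sim <- function(object, ...) {
  lab <- classify_sim(object)
  fd <- tryCatch(
    dominant_frequency(object$mean_field, object$sample_rate,
                       transient = object$config$transient),
    error = function(e) NA_real_)
  out <- list(label = lab, dominant_frequency = fd,
              diverged = object$diverged,
              mean_level = mean(post_transient(object)),
              h7 = object$params$h[7], h8 = object$params$h[8],
              protocol = object$protocol$kind)
  class(out) <- "summary.ctmbc_sim"
  out
}

#' @export
print.summary.ctmbc_sim <- function(x, ...) {
  cat(sprintf("state %s, dominant frequency %.2f Hz, mean level %.3f\n",
              as.character(x$label), x$dominant_frequency, x$mean_level))
  cat(sprintf("  (h7 = %g, h8 = %g, protocol %s%s)\n", x$h7, x$h8,
              x$protocol, if (x$diverged) ", diverged" else ""))
  invisible(x)
}

#' @export
plot.ctmbc_sim <- function(x, which = c("mean_field", "states", "stimulus"),
                           ...) {
  which <- match.arg(which)
  if (which == "mean_field") {
    graphics::plot(x$time, x$mean_field, type = "l",
                   xlab = "time (s)", ylab = "0.5 (PY1 + IN1)", ...)
  } else if (which == "states") {
    old <- graphics::par(mfrow = c(4, 2), mar = c(2.5, 4, 1, 1))
    on.exit(graphics::par(old))
    for (nm in colnames(x$states)) {
      graphics::plot(x$time, x$states[, nm], type = "l",
                     xlab = "", ylab = nm)
    }
  } else {
    graphics::plot(x$time, x$stim1, type = "l", col = "firebrick",
                   xlab = "time (s)", ylab = "gated current", ...)
    graphics::lines(x$time, x$stim2, col = "steelblue")
    graphics::legend("topright", legend = c("TRN1", "TRN2"), lty = 1,
                     col = c("firebrick", "steelblue"), bty = "n")
  }
  invisible(x)
}

#' @export
as.data.frame.ctmbc_sim <- function(x, ...) {
  data.frame(time = x$time, x$states,
             stim_trn1 = x$stim1, stim_trn2 = x$stim2,
             mean_field = x$mean_field, mean_field2 = x$mean_field2)
}

# post-transient mean-field segment of a run
post_transient <- function(sim, signal = sim$mean_field) {
  keep <- sim$time >= sim$config$transient
  signal[keep]
}
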