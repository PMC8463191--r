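#' Classifier settings
#'
#' Free parameters of the dynamical-state classifier.  None of these are
#' dictated by the model itself; the defaults were fixed once so that the
#' classifier reproduces the published regime assignments along the
#' h7 bifurcation axis, and are exposed here for sensitivity analysis.
#'
#' @param amp_tol peak-to-peak amplitude below which a post-transient
#'   trace counts as a fixed point.
#' @param sat_threshold mean-field level separating the high-saturated
#'   branch (state I) from the low-firing branch (state IV); the model's
#'   two stationary branches sit near 0.46 and 0.16, so the default 0.3 is
#'   their midpoint.
#' @param prominence minimum prominence of a local maximum, as a fraction
#'   of the segment's peak-to-peak amplitude, for it to count as a
#'   distinct spike.
#' @param swd_band dominant-frequency band (Hz) of spike-wave discharges.
#' @param min_spikes local maxima per fundamental period required for the
#'   spike-wave label (2 = one spike plus one wave).
#' @param spike_tol slack on the spikes-per-period count absorbing
#'   windowing effects at the segment edges.
#' @param freq_band search band (Hz) for the dominant spectral peak.
#' @return a list of class \code{"ctmbc_classify_control"}.
#' @export
classify_control <- function(amp_tol = 0.01, sat_threshold = 0.3,
                             prominence = 0.15, swd_band = c(2, 4),
                             min_spikes = 2, spike_tol = 0.1,
                             freq_band = c(0.5, 50)) {
  structure(list(amp_tol = amp_tol, sat_threshold = sat_threshold,
                 prominence = prominence, swd_band = swd_band,
                 min_spikes = min_spikes, spike_tol = spike_tol,
                 freq_band = freq_band),
            class = "ctmbc_classify_control")
}

#' Dominant frequency of a mean-field trace
#'
#' Frequency of the largest peak of the mean-removed periodogram inside
#' \code{freq_band} (default (0.5, 50] Hz), computed on the post-transient
#' segment.  Traces whose peak-to-peak amplitude falls below the
#' fixed-point tolerance return 0.
#'
#' @param x numeric trace (a mean-field series).
#' @param sample_rate sampling rate of \code{x} (Hz).
#' @param transient leading interval to discard (s).
#' @param control a \code{\link{classify_control}} list.
#' @return dominant frequency in Hz (0 for a fixed point).
#' @examples
#' t <- seq(0, 20, by = 1/400)
#' dominant_frequency(sin(2 * pi * 3 * t), 400)   # 3 Hz
#' @export
dominant_frequency <- function(x, sample_rate, transient = 0,
                               control = classify_control()) {
  seg <- trim_transient(x, sample_rate, transient)
  if (length(seg) < 5 * sample_rate) {
    stop("post-transient segment must be at least 5 s long")
  }
  if (!all(is.finite(seg))) return(NA_real_)
  if (diff(range(seg)) < control$amp_tol) return(0)
  peak_frequency(seg, sample_rate, control$freq_band)
}

trim_transient <- function(x, sample_rate, transient) {
  n_drop <- floor(transient * sample_rate)
  if (n_drop >= length(x)) stop("transient longer than the trace")
  if (n_drop > 0) x[-seq_len(n_drop)] else x
}

peak_frequency <- function(seg, sample_rate, band) {
  n <- length(seg)
  y <- seg - mean(seg)
  p <- Mod(stats::fft(y))^2
  freq <- (seq_len(n) - 1) * sample_rate / n
  half <- seq_len(floor(n / 2))
  freq <- freq[half]; p <- p[half]
  sel <- freq > band[1] & freq <= band[2]
  if (!any(sel)) return(0)
  freq[sel][which.max(p[sel])]
}

# local maxima whose prominence (height above the higher flanking minimum)
# exceeds `prom`; returns indices
prominent_maxima <- function(seg, prom) {
  d <- diff(seg)
  up <- d[-length(d)] > 0 & d[-1] <= 0
  down <- d[-length(d)] < 0 & d[-1] >= 0
  imax <- which(up) + 1L
  imin <- which(down) + 1L
  if (length(imax) == 0) return(integer(0))
  keep <- vapply(imax, function(i) {
    lo <- imin[imin < i]; hi <- imin[imin > i]
    ref <- max(if (length(lo)) seg[lo[length(lo)]] else seg[1],
               if (length(hi)) seg[hi[1]] else seg[length(seg)])
    seg[i] - ref > prom
  }, logical(1))
  imax[keep]
}

#' Classify the dynamical state of a mean-field trace
#'
#' Assigns one of the four regimes of the model (or \code{"divergent"}):
#' \describe{
#'   \item{I}{high saturated: fixed point above the saturation threshold.}
#'   \item{II}{simple oscillation: limit cycle with one spike per period,
#'     or dominant frequency outside the 2-4 Hz band.}
#'   \item{III}{spike-wave discharge (SWD): dominant frequency in 2-4 Hz
#'     with at least two distinct local maxima per fundamental period
#'     (spike plus wave).}
#'   \item{IV}{low firing: fixed point below the saturation threshold.}
#' }
#' The decision rule: a post-transient peak-to-peak amplitude below
#' \code{amp_tol} is a fixed point, split I/IV by the mean level;
#' otherwise the trace is oscillatory, and the spike count per period
#' (prominence-filtered local maxima divided by the number of fundamental
#' periods in the segment) together with the dominant frequency separates
#' III from II.
#'
#' @inheritParams dominant_frequency
#' @return a one-element factor with levels
#'   \code{c("I", "II", "III", "IV", "divergent")}.
#' @export
classify_state <- function(x, sample_rate, transient = 0,
                           control = classify_control()) {
  lev <- c("I", "II", "III", "IV", "divergent")
  seg <- trim_transient(x, sample_rate, transient)
  if (length(seg) < 5 * sample_rate) {
    stop("post-transient segment must be at least 5 s long")
  }
  if (!all(is.finite(seg))) return(factor("divergent", levels = lev))
  ptp <- diff(range(seg))
  if (ptp < control$amp_tol) {
    lab <- if (mean(seg) > control$sat_threshold) "I" else "IV"
    return(factor(lab, levels = lev))
  }
  fd <- peak_frequency(seg, sample_rate, control$freq_band)
  n_per <- length(seg) / sample_rate * fd
  n_max <- length(prominent_maxima(seg, control$prominence * ptp))
  spikes <- if (n_per > 0) n_max / n_per else 0
  swd <- fd >= control$swd_band[1] && fd <= control$swd_band[2] &&
    spikes >= control$min_spikes - control$spike_tol
  factor(if (swd) "III" else "II", levels = lev)
}

#' @rdname classify_state
#' @param sim a \code{ctmbc_sim} object; its mean-field trace, sample
#'   rate, transient and divergence flag are used.
#' @export
classify_sim <- function(sim, control = classify_control()) {
  lev <- c("I", "II", "III", "IV", "divergent")
  if (sim$diverged) return(factor("divergent", levels = lev))
  classify_state(sim$mean_field, sim$sample_rate,
                 transient = sim$config$transient, control = control)
}

#' One-parameter bifurcation scan
#'
#' For each value of h7 (at fixed h8) the model is integrated once and
#' the post-transient local extrema of the module-I mean field are
#' collected, yielding the classic extrema-versus-parameter bifurcation
#' portrait: a fixed point contributes a single repeated value, a simple
#' oscillation two bands (one maximum, one minimum per period), and a
#' spike-wave cycle at least four distinct bands.
#'
#' @param params a \code{\link{ctmbc_params}} object (h7 is overridden
#'   per scan point).
#' @param h7_values numeric vector of h7 values (at least 2).
#' @param h8 fixed h8 value.
#' @param config a \code{\link{sim_config}}; a single run per point is
#'   used (the initial state comes from the config seed).
#' @param protocol stimulation protocol, default none.
#' @param control classifier settings used for the per-point state label.
#' @return an object of class \code{"ctmbc_bifurcation"}: a data frame
#'   with columns \code{h7}, \code{value}, \code{type} ("max"/"min"),
#'   plus per-point labels in \code{attr(, "labels")}.
#' @export
bifurcation_scan <- function(params, h7_values, h8, config = sim_config(),
                             protocol = stim_none(),
                             control = classify_control()) {
  stopifnot(length(h7_values) >= 2)
  inits <- draw_initials(1, config)
  rows <- list(); labels <- character(length(h7_values))
  for (i in seq_along(h7_values)) {
    p <- params; p$h[7] <- h7_values[i]; p$h[8] <- h8
    sim <- ctmbc_simulate(p, protocol, config, initial = inits[1, ])
    labels[i] <- as.character(classify_sim(sim, control))
    if (sim$diverged) next
    seg <- post_transient(sim)
    ptp <- diff(range(seg))
    if (ptp < control$amp_tol) {
      rows[[length(rows) + 1]] <- data.frame(
        h7 = h7_values[i], value = mean(seg), type = "max")
      rows[[length(rows) + 1]] <- data.frame(
        h7 = h7_values[i], value = mean(seg), type = "min")
    } else {
      prom <- control$prominence * ptp
      imax <- prominent_maxima(seg, prom)
      imin <- prominent_maxima(-seg, prom)
      rows[[length(rows) + 1]] <- data.frame(
        h7 = h7_values[i],
        value = c(seg[imax], seg[imin]),
        type = rep(c("max", "min"), c(length(imax), length(imin))))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  attr(out, "h7_values") <- h7_values
  attr(out, "h8") <- h8
  class(out) <- c("ctmbc_bifurcation", "data.frame")
  out
}

#' @export
plot.ctmbc_bifurcation <- function(x, ...) {
  graphics::plot(x$h7, x$value,
                 pch = ".", cex = 2,
                 col = ifelse(x$type == "max", "firebrick", "steelblue"),
                 xlab = expression(h[7]), ylab = "mean-field extrema", ...)
  invisible(x)
}

#' Two-parameter state map over the (h7, h8) plane
#'
#' Runs a seeded ensemble at every grid cell, labels each run with
#' \code{\link{classify_state}}, combines the repeats by majority vote
#' (ties broken toward the more pathological state: SWD over simple
#' oscillation over fixed points), and records the median dominant
#' frequency of the non-divergent runs.  The SWD area fraction is the
#' percentage of non-divergent cells labelled III.
#'
#' For speed the per-run trajectories are thinned to about 500 Hz before
#' classification (the integrator still steps at \code{config$dt}); the
#' spike-wave rhythm lives at 2-4 Hz, so this loses nothing.
#'
#' @param params a \code{\link{ctmbc_params}} object; h7/h8 are set per
#'   cell.
#' @param h7,h8 grid values (numeric vectors).
#' @param protocol stimulation protocol applied at every cell.
#' @param config a \code{\link{sim_config}}; \code{n_repeats} runs per
#'   cell.
#' @param control classifier settings.
#' @param include_divergent logical; count divergent cells in the area
#'   denominator (default FALSE).
#' @param progress print one line per grid row.
#' @return an object of class \code{"ctmbc_map"}: list with \code{h7},
#'   \code{h8}, \code{labels} (character matrix h7 x h8), \code{freq}
#'   (median dominant frequency, Hz), \code{swd_area} (percent),
#'   \code{protocol}, \code{params}, \code{config}.
#' @export
sweep_2d <- function(params, h7 = seq(1.5, 2.5, length.out = 41),
                     h8 = seq(9, 11, length.out = 41),
                     protocol = stim_none(), config = sim_config(),
                     control = classify_control(),
                     include_divergent = FALSE, progress = FALSE) {
  rec_every <- max(1L, as.integer(round(1 / (500 * config$dt))))
  cfg <- config; cfg$record_every <- rec_every
  # one seeded stream supplies independent initial states for every
  # (cell, repeat) pair, so cells are not tied to a shared set of
  # initial conditions; identical (seed, grid, config) still reproduce
  # the identical map, and protocols compared on the same grid and seed
  # see the same initial states cell for cell
  inits <- draw_initials(config$n_repeats * length(h7) * length(h8),
                         config)
  labs <- matrix(NA_character_, length(h7), length(h8))
  freq <- matrix(NA_real_, length(h7), length(h8))
  p <- params
  for (i in seq_along(h7)) {
    for (j in seq_along(h8)) {
      p$h[7] <- h7[i]; p$h[8] <- h8[j]
      run_lab <- character(cfg$n_repeats)
      run_fd <- rep(NA_real_, cfg$n_repeats)
      cell0 <- ((i - 1) * length(h8) + (j - 1)) * cfg$n_repeats
      for (r in seq_len(cfg$n_repeats)) {
        sim <- ctmbc_simulate(p, protocol, cfg,
                              initial = inits[cell0 + r, ])
        run_lab[r] <- as.character(classify_sim(sim, control))
        if (!sim$diverged) {
          run_fd[r] <- dominant_frequency(sim$mean_field, sim$sample_rate,
                                          cfg$transient, control)
        }
      }
      labs[i, j] <- majority_label(run_lab)
      freq[i, j] <- stats::median(run_fd, na.rm = TRUE)
    }
    if (progress) {
      message(sprintf("h7 = %.3f done (%d of %d rows)", h7[i], i,
                      length(h7)))
    }
  }
  out <- list(h7 = h7, h8 = h8,
              labels = labs, freq = freq,
              swd_area = swd_area_from_labels(labs, include_divergent),
              protocol = protocol, params = params, config = config,
              control = control)
  class(out) <- "ctmbc_map"
  out
}

# majority vote with ties broken toward the more pathological state
majority_label <- function(labels) {
  rank <- c(III = 5, II = 4, IV = 3, I = 2, divergent = 1)
  tab <- table(labels)
  cand <- names(tab)[tab == max(tab)]
  cand[order(rank[cand], decreasing = TRUE)][1]
}

swd_area_from_labels <- function(labs, include_divergent = FALSE) {
  n <- if (include_divergent) length(labs) else sum(labs != "divergent")
  if (n == 0) return(NA_real_)
  100 * sum(labs == "III") / n
}

#' SWD area fraction of a state map
#'
#' Percentage of (non-divergent) grid cells labelled as 2-4 Hz
#' spike-wave discharge.
#'
#' @param map a \code{ctmbc_map} object.
#' @param include_divergent count divergent cells in the denominator.
#' @return scalar percentage in [0, 100].
#' @export
swd_area <- function(map, include_divergent = FALSE) {
  stopifnot(inherits(map, "ctmbc_map"))
  swd_area_from_labels(as.character(map$labels), include_divergent)
}

#' @export
print.ctmbc_map <- function(x, ...) {
  cat(sprintf("State map: %d x %d cells over h7 [%g, %g] x h8 [%g, %g]\n",
              length(x$h7), length(x$h8), min(x$h7), max(x$h7),
              min(x$h8), max(x$h8)))
  cat("  protocol:", x$protocol$kind,
      " topology:", x$params$topology, "\n")
  print(table(state = as.character(x$labels)))
  cat(sprintf("  SWD area: %.1f%%\n", x$swd_area))
  invisible(x)
}

#' @export
plot.ctmbc_map <- function(x, which = c("states", "frequency"), ...) {
  which <- match.arg(which)
  if (which == "states") {
    lev <- c("I", "II", "III", "IV", "divergent")
    z <- matrix(match(x$labels, lev), length(x$h7), length(x$h8))
    cols <- c("white", "firebrick", "gold", "black", "grey50")
    graphics::image(x$h7, x$h8, z, zlim = c(1, 5),
                    col = cols, xlab = expression(h[7]),
                    ylab = expression(h[8]), ...)
    graphics::legend("topright",
                     legend = c("I saturated", "II oscillation", "III SWD",
                                "IV low firing", "divergent"),
                     fill = cols, bg = "white", cex = 0.7)
  } else {
    graphics::image(x$h7, x$h8, x$freq, xlab = expression(h[7]),
                    ylab = expression(h[8]), ...)
  }
  invisible(x)
}

#' @export
as.data.frame.ctmbc_map <- function(x, ...) {
  grid <- expand.grid(h7 = x$h7, h8 = x$h8)
  idx <- cbind(match(grid$h7, x$h7), match(grid$h8, x$h8))
  grid$label <- x$labels[idx]
  grid$dominant_Hz <- x$freq[idx]
  grid
}

#' Compare therapy protocols on the (h7, h8) plane
#'
#' Computes the state map for each protocol on the same grid, seeds and
#' classifier as an unstimulated baseline map, and derives the two
#' published evaluation indices: the SWD percentage reduction relative to
#' the baseline SWD area, and the RMS stimulation current (the total
#' gated current beta1*u + beta2*u over the post-transient window).  The
#' energy expenditure column expresses each RMS as a percentage of a
#' baseline scheme; no normalization is canonical, so the default
#' baseline is the maximum-RMS scheme and raw RMS values are always
#' reported.
#'
#' @param params a \code{\link{ctmbc_params}} object.
#' @param protocols named list of \code{\link{stim_protocol}} objects.
#' @param h7,h8 grid values shared by all maps.
#' @param config a \code{\link{sim_config}}.
#' @param control classifier settings.
#' @param baseline_map optional precomputed unstimulated \code{ctmbc_map}
#'   on the identical grid (recomputed when NULL).
#' @param progress print per-map progress.
#' @return an object of class \code{"ctmbc_therapy"}: a data frame with
#'   one row per scheme (plus the baseline) and columns
#'   \code{swd_area}, \code{reduction}, \code{rms_current},
#'   \code{ec_percent}; the maps are attached as \code{attr(, "maps")}.
#' @export
therapy_comparison <- function(params, protocols,
                               h7 = seq(1.5, 2.5, length.out = 41),
                               h8 = seq(9, 11, length.out = 41),
                               config = sim_config(),
                               control = classify_control(),
                               baseline_map = NULL, progress = FALSE) {
  stopifnot(is.list(protocols), length(protocols) >= 1)
  if (is.null(names(protocols)) || any(names(protocols) == "")) {
    stop("protocols must be a named list")
  }
  if (is.null(baseline_map)) {
    baseline_map <- sweep_2d(params, h7, h8, stim_none(), config, control,
                             progress = progress)
  } else {
    if (!isTRUE(all.equal(baseline_map$h7, h7)) ||
        !isTRUE(all.equal(baseline_map$h8, h8))) {
      stop("baseline map grid does not match the requested grid")
    }
  }
  base_area <- baseline_map$swd_area
  maps <- list(none = baseline_map)
  rows <- data.frame(scheme = "none", swd_area = base_area,
                     reduction = 0, rms_current = 0,
                     stringsAsFactors = FALSE)
  # RMS of the total gated current on the post-transient window;
  # the stimulus is state-independent, so it is evaluated analytically
  tg <- seq(config$transient, config$duration, by = config$dt)
  for (nm in names(protocols)) {
    m <- sweep_2d(params, h7, h8, protocols[[nm]], config, control,
                  progress = progress)
    maps[[nm]] <- m
    cur <- stim_currents(tg, protocols[[nm]])
    rows <- rbind(rows, data.frame(
      scheme = nm, swd_area = m$swd_area,
      reduction = 100 * (base_area - m$swd_area) / base_area,
      rms_current = rms_current(cur[, 1] + cur[, 2]),
      stringsAsFactors = FALSE))
  }
  ref <- max(rows$rms_current)
  rows$ec_percent <- if (ref > 0) 100 * rows$rms_current / ref else 0
  class(rows) <- c("ctmbc_therapy", "data.frame")
  attr(rows, "maps") <- maps
  rows
}

#' Write a state map to disk
#'
#' Exports the map as a long-format CSV (h7, h8, label, dominant_Hz)
#' plus a small JSON summary (grid, protocol, SWD area) when the
#' jsonlite package is available.
#'
#' @param map a \code{ctmbc_map} object.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_map <- function(map, dir) {
  stopifnot(inherits(map, "ctmbc_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(map), file.path(dir, "state_map.csv"),
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(h7_range = range(map$h7), h8_range = range(map$h8),
           cells = length(map$h7) * length(map$h8),
           protocol = map$protocol$kind, topology = map$params$topology,
           swd_area_percent = map$swd_area),
      file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @export
print.ctmbc_therapy <- function(x, ...) {
  cat("Therapy comparison (SWD area %, reduction vs baseline %, RMS",
      "current, EC % of max-RMS scheme)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
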