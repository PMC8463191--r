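test_that("decoupled relaxation equilibrium is preserved by the integrator", {
  p <- ctmbc_params(h = rep(0, 9))
  fp <- rep(p$eps, 2)
  cfg <- sim_config(duration = 2, transient = 0, record_every = 40L)
  sim <- ctmbc_simulate(p, config = cfg, initial = fp)
  expect_false(sim$diverged)
  drift <- apply(abs(sweep(sim$states, 2, fp)), 2, max)
  expect_true(all(drift < 1e-10))
})

test_that("module-symmetric initial states stay on the symmetry manifold", {
  p <- ctmbc_params(h7 = 2.3, h8 = 10.1)
  init <- population_state(py1 = 0.2, in1 = -0.4, srn1 = 0.1, trn1 = -0.7,
                           py2 = 0.2, in2 = -0.4, srn2 = 0.1, trn2 = -0.7)
  cfg <- sim_config(duration = 5, transient = 0, record_every = 8L)
  sim <- ctmbc_simulate(p, config = cfg, initial = init)
  expect_equal(sim$states[, "py1"], sim$states[, "py2"], tolerance = 1e-12)
  expect_equal(sim$states[, "trn1"], sim$states[, "trn2"], tolerance = 1e-12)
  expect_equal(sim$mean_field, sim$mean_field2, tolerance = 1e-12)
})

test_that("integrator converges at fourth order in the step size", {
  p <- ctmbc_params(h7 = 2.1, h8 = 10.2)
  init <- population_state(py1 = 0.1, in1 = -0.2, srn1 = 0.3, trn1 = -0.4,
                           py2 = -0.1, in2 = 0.2, srn2 = -0.3, trn2 = 0.4)
  final_state <- function(dt) {
    cfg <- sim_config(dt = dt, duration = 2, transient = 0,
                      record_every = as.integer(round(2 / dt)))
    sim <- ctmbc_simulate(p, config = cfg, initial = init)
    sim$states[nrow(sim$states), ]
  }
  y1 <- final_state(0.5e-3)
  y2 <- final_state(0.25e-3)
  y3 <- final_state(0.125e-3)
  e12 <- sqrt(sum((y1 - y2)^2))
  e23 <- sqrt(sum((y2 - y3)^2))
  # halving dt should shrink the difference by about 2^4
  expect_gt(e12 / e23, 8)
  expect_lt(e12 / e23, 32)
})

test_that("mean field equals the average of its two source trajectories", {
  p <- ctmbc_params(h7 = 2.5, h8 = 9.2)
  sim <- ctmbc_simulate(p, config = fast_config())
  expect_equal(sim$mean_field,
               0.5 * (sim$states[, "py1"] + sim$states[, "in1"]))
  expect_equal(length(sim$time), nrow(sim$states))
  expect_true(all(is.finite(sim$states)))
})

test_that("recorded stimulus traces equal the waveform on the same grid", {
  p <- ctmbc_params(h7 = 2.0, h8 = 10.0)
  cfg <- sim_config(duration = 1, transient = 0, record_every = 4L)
  for (proto in list(stim_protocol("dbs"),
                     stim_protocol("cbbp"),
                     stim_protocol("crs", crs = c(3, 2)))) {
    sim <- ctmbc_simulate(p, proto, cfg)
    cur <- stim_currents(sim$time, proto)
    expect_equal(sim$stim1, unname(cur[, 1]))
    expect_equal(sim$stim2, unname(cur[, 2]))
  }
})

test_that("RMS of the recorded DBS trace matches the analytic value", {
  p <- ctmbc_params(h7 = 2.0, h8 = 10.0)
  cfg <- sim_config(duration = 20, transient = 10)
  sim <- ctmbc_simulate(p, stim_protocol("dbs", amplitude = 3), cfg)
  keep <- sim$time >= cfg$transient
  rms <- rms_current(sim$stim1[keep])
  expect_equal(rms, 3 * sqrt(0.004 * 130), tolerance = 1e-3)
})

test_that("ensembles are bit-reproducible and reduce to single runs", {
  p <- ctmbc_params(h7 = 2.5, h8 = 9.2)
  cfg <- fast_config()
  e1 <- run_ensemble(p, config = cfg)
  e2 <- run_ensemble(p, config = cfg)
  expect_identical(lapply(e1$runs, `[[`, "states"),
                   lapply(e2$runs, `[[`, "states"))
  cfg1 <- fast_config(); cfg1$n_repeats <- 1L
  e3 <- run_ensemble(p, config = cfg1)
  init <- ctmbc:::draw_initials(1, cfg1)[1, ]
  solo <- ctmbc_simulate(p, config = cfg1, initial = init)
  expect_identical(e3$runs[[1]]$states, solo$states)
})

test_that("ensemble dominant frequencies agree in the SWD regime", {
  p <- ctmbc_params(h7 = 2.5, h8 = 9.2)
  cfg <- sim_config(duration = 15, transient = 5, n_repeats = 5, seed = 7,
                    record_every = 8L)
  ens <- run_ensemble(p, config = cfg)
  fds <- vapply(ens$runs, function(s) {
    dominant_frequency(s$mean_field, s$sample_rate, cfg$transient)
  }, numeric(1))
  # the SWD attractor is global here: all runs land on the same rhythm
  expect_lt(max(fds) - min(fds), 0.2)
  expect_true(all(fds >= 2 & fds <= 4))
})

test_that("divergent runs are flagged and truncated, not errors", {
  p <- ctmbc_params(h7 = 2.0, h8 = 10.0)
  cfg <- sim_config(duration = 2, transient = 0, overflow_guard = 0.5)
  sim <- ctmbc_simulate(p, config = cfg,
                        initial = rep(0.4, 8))
  expect_true(sim$diverged)
  expect_true(is.finite(sim$diverge_time))
  expect_lt(max(sim$time), 2)
})

test_that("simulation configs are validated", {
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(transient = 40, duration = 30))
  expect_error(sim_config(n_repeats = 0))
  expect_error(ctmbc_simulate(ctmbc_params(), initial = rep(NA_real_, 8)),
               "finite")
})
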