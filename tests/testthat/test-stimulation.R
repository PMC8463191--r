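test_that("DBS pulse train has the published on/off structure", {
  p <- stim_protocol("dbs", amplitude = 2, frequency = 130,
                     pulse_width = 0.004)
  # pulse occupies the first 4 ms of each ~7.69 ms period
  expect_equal(dbs_waveform(0.001, p), 2)
  expect_equal(dbs_waveform(0.006, p), 0)
  expect_equal(dbs_waveform(0.001 + 5 / 130, p), 2)
  # zero amplitude kills the train
  p0 <- stim_protocol("dbs", amplitude = 0)
  expect_true(all(dbs_waveform(seq(0, 0.1, 1e-4), p0) == 0))
  expect_error(stim_protocol("dbs", pulse_width = 1), "pulse_width")
  expect_error(dbs_waveform(-0.1, p), "non-negative")
})

test_that("waveforms are exactly periodic on the sample grid", {
  t <- seq(0, 0.05, by = 1.25e-4)
  dbs <- stim_protocol("dbs")
  cbbp <- stim_protocol("cbbp")
  expect_equal(dbs_waveform(t + 3 * dbs$period, dbs), dbs_waveform(t, dbs))
  expect_equal(cbbp_waveform(t + 2 * cbbp$cbbp_period, cbbp),
               cbbp_waveform(t, cbbp))
})

test_that("DBS RMS over whole periods matches the analytic alpha*sqrt(duty)", {
  p <- stim_protocol("dbs", amplitude = 2, frequency = 130,
                     pulse_width = 0.004)
  # numerical quadrature of u^2 over 10 periods as the oracle
  n <- 200000
  t <- (seq_len(n) - 0.5) / n * 10 * p$period
  rms_quad <- sqrt(mean(dbs_waveform(t, p)^2))
  analytic <- 2 * sqrt(0.004 * 130)
  expect_equal(analytic, 2 * sqrt(0.52), tolerance = 1e-12)
  expect_equal(rms_quad, analytic, tolerance = 1e-4)
})

test_that("CBBP waveform is charge balanced with the derived cathodic level", {
  p <- stim_protocol("cbbp", amplitude = 2, frequency = 130,
                     pulse_width = 0.004)
  Tp <- p$cbbp_period
  # cathodic amplitude -alpha*delta/(T-delta)
  expect_equal(cbbp_waveform(Tp - 1e-6, p), -2 * 0.004 / (Tp - 0.004),
               tolerance = 1e-9)
  expect_equal(cbbp_waveform(5 * Tp + 0.002, p), 2)  # anodic phase membership
  # net charge per period: quadrature at sub-microsecond resolution
  dt <- Tp / 1e6
  t <- (seq_len(1e6) - 0.5) * dt
  charge <- sum(cbbp_waveform(t, p)) * dt
  expect_lt(abs(charge), 1e-12 * 2 * Tp)
  expect_error(stim_protocol("cbbp", pulse_width = 1), "pulse_width")
})

test_that("literal-form CBBP uses the printed delta-valued amplitudes", {
  p <- stim_protocol("cbbp", frequency = 130, pulse_width = 0.004,
                     cbbp_literal = TRUE)
  expect_equal(cbbp_waveform(0.001, p), 0.004)
  expect_equal(cbbp_waveform(0.005, p), -0.004 / (p$cbbp_period - 0.004),
               tolerance = 1e-12)
  # the printed form carries a net hyperpolarizing charge per period
  tq <- (seq_len(1e5) - 0.5) * p$cbbp_period / 1e5
  expect_lt(mean(cbbp_waveform(tq, p)), -0.5)
})

test_that("CRS 1:0 alternates targets every cycle starting with TRN1", {
  p <- stim_protocol("crs", crs = c(1, 0))
  cyc <- p$crs_cycle
  mid <- cyc * (0:5) + cyc / 2
  g <- crs_gates(mid, p)
  expect_equal(g[, "beta1"], c(1, 0, 1, 0, 1, 0))
  expect_equal(g[, "beta2"], c(0, 1, 0, 1, 0, 1))
})

test_that("CRS 3:2 stimulates three alternating cycles then pauses two", {
  p <- stim_protocol("crs", crs = c(3, 2))
  cyc <- p$crs_cycle
  mid <- cyc * (0:9) + cyc / 2
  g <- crs_gates(mid, p)
  expect_equal(g[, "beta1"], c(1, 0, 1, 0, 0, 0, 1, 0, 0, 0))
  expect_equal(g[, "beta2"], c(0, 1, 0, 0, 0, 1, 0, 1, 0, 0))
})

test_that("CRS gates are binary, mutually exclusive and dt-independent", {
  p <- stim_protocol("crs", crs = c(3, 2))
  set.seed(21)
  t <- runif(500, 0, 1)
  g <- crs_gates(t, p)
  expect_true(all(g %in% c(0, 1)))
  expect_true(all(g[, 1] * g[, 2] == 0))
  # gate value depends only on the cycle index, not on position inside it
  cyc_start <- floor(t / p$crs_cycle) * p$crs_cycle
  g2 <- crs_gates(cyc_start + p$crs_cycle * 0.123, p)
  expect_equal(g, g2, ignore_attr = TRUE)
  expect_error(stim_protocol("crs", crs = c(0, 2)), "crs")
})

test_that("rms_current matches closed forms and its invariances", {
  expect_equal(rms_current(rep(3, 17)), 3)
  expect_equal(rms_current(rep(-3, 17)), 3)
  expect_equal(rms_current(numeric(5)), 0)
  expect_error(rms_current(numeric(0)), "at least one")
  # square wave amplitude alpha, duty d -> alpha*sqrt(d)
  x <- c(rep(2, 26), rep(0, 74))
  expect_equal(rms_current(x), 2 * sqrt(0.26))
  set.seed(9)
  y <- rnorm(100)
  expect_equal(rms_current(sample(y)), rms_current(y))
  expect_equal(rms_current(3.7 * y), 3.7 * rms_current(y))
})

test_that("stim_currents gates DBS/CBBP to both targets and CRS to one", {
  t <- seq(0, 0.1, by = 1e-4)
  dbs <- stim_protocol("dbs")
  cur <- stim_currents(t, dbs)
  expect_equal(cur[, 1], cur[, 2])
  expect_equal(cur[, 1], dbs_waveform(t, dbs), ignore_attr = TRUE)
  crs <- stim_protocol("crs", crs = c(1, 0))
  cc <- stim_currents(t, crs)
  expect_true(all(cc[, 1] * cc[, 2] == 0))
  none <- stim_none()
  expect_true(all(stim_currents(t, none) == 0))
})

test_that("waveform export writes a readable two-column table", {
  p <- stim_protocol("dbs")
  path <- tempfile(fileext = ".csv")
  write_waveform(p, path)
  tab <- read.csv(path)
  expect_named(tab, c("time", "trn1", "trn2"))
  expect_equal(tab$trn1, dbs_waveform(tab$time, p))
})
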