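test_that("dominant frequency resolves single tones and mixtures", {
  fs <- 4000
  t <- seq(0, 20, by = 1 / fs)
  expect_equal(dominant_frequency(sin(2 * pi * 3 * t), fs), 3,
               tolerance = 0.05 / 3)
  expect_identical(dominant_frequency(rep(0.7, length(t)), fs), 0)
  # dominant peak of a two-tone mixture is the stronger low component
  x <- 2 * sin(2 * pi * 2.5 * t) + sin(2 * pi * 8 * t)
  expect_equal(dominant_frequency(x, fs), 2.5, tolerance = 0.05 / 2.5)
  expect_error(dominant_frequency(sin(t[1:400]), fs), "at least 5 s")
})

test_that("classifier labels the analytic fixture traces correctly", {
  fx <- synthetic_traces(seed = 3)
  for (nm in names(fx)) {
    f <- fx[[nm]]
    if (is.na(f$label)) next
    lab <- classify_state(f$trace, 500)
    expect_identical(as.character(lab), f$label, label = nm)
    fd <- dominant_frequency(f$trace, 500)
    expect_equal(fd, f$frequency, tolerance = 0.06, label = paste(nm, "Hz"))
  }
})

test_that("classifier output is a total function over the four states", {
  fx <- synthetic_traces(seed = 8)
  labs <- vapply(fx, function(f) as.character(classify_state(f$trace, 500)),
                 character(1))
  expect_true(all(labs %in% c("I", "II", "III", "IV")))
  # non-finite traces are flagged divergent
  bad <- c(rep(0.2, 4000), rep(Inf, 1000))
  expect_identical(as.character(classify_state(bad, 500)), "divergent")
})

test_that("classifier separates the published regime anchors on the h7 axis", {
  cfg <- sim_config(seed = 1, record_every = 8L)
  lab_at <- function(h7, h8) {
    as.character(classify_sim(
      ctmbc_simulate(ctmbc_params(h7 = h7, h8 = h8), config = cfg)))
  }
  expect_identical(lab_at(1.5, 9.2), "I")
  expect_identical(lab_at(2.1, 9.2), "II")
  expect_identical(lab_at(2.5, 9.2), "III")
  expect_identical(lab_at(1.5, 10.2), "II")
  expect_identical(lab_at(2.1, 10.2), "III")
})

test_that("bifurcation scan shows the I -> II -> III sequence at h8 = 9.2", {
  cfg <- sim_config(duration = 20, transient = 10, seed = 2,
                    record_every = 8L)
  scan <- bifurcation_scan(ctmbc_params(), seq(1.5, 2.5, by = 0.25),
                           h8 = 9.2, config = cfg)
  labs <- attr(scan, "labels")
  # ordered regime sequence with recorded transitions
  expect_identical(labs[1], "I")
  expect_identical(labs[length(labs)], "III")
  expect_identical(rle(labs)$values, c("I", "II", "III"))
  # fixed-point cells contribute coincident extrema
  fp <- subset(scan, h7 == 1.5)
  expect_lt(diff(range(fp$value)), 0.01)
  # spike-wave cells carry at least 4 extrema bands (2 maxima + 2 minima
  # per period)
  swd <- subset(scan, h7 == 2.5)
  expect_gte(length(unique(round(swd$value, 3))), 4)
  # roughly two prominent maxima per ~2.5 Hz period over the 10 s window
  expect_gt(sum(swd$type == "max"), 1.5 * 10 * 2)
})

test_that("small state maps are complete, bounded and reproducible", {
  cfg <- sim_config(duration = 15, transient = 5, n_repeats = 2, seed = 5)
  map <- sweep_2d(ctmbc_params(), h7 = c(1.5, 2.0, 2.5),
                  h8 = c(9.2, 10.2, 11), config = cfg)
  expect_true(all(!is.na(map$labels)))
  expect_gte(map$swd_area, 0)
  expect_lte(map$swd_area, 100)
  map2 <- sweep_2d(ctmbc_params(), h7 = c(1.5, 2.0, 2.5),
                   h8 = c(9.2, 10.2, 11), config = cfg)
  expect_identical(as.character(map$labels), as.character(map2$labels))
  df <- as.data.frame(map)
  expect_identical(nrow(df), 9L)
  expect_named(df, c("h7", "h8", "label", "dominant_Hz"))
})

test_that("SWD area counts III cells over the non-divergent denominator", {
  labs <- matrix(c("III", "III", "II", "I", "IV", "divergent"), 2, 3)
  expect_equal(ctmbc:::swd_area_from_labels(labs), 100 * 2 / 5)
  expect_equal(ctmbc:::swd_area_from_labels(labs, include_divergent = TRUE),
               100 * 2 / 6)
  all3 <- matrix("III", 4, 4)
  expect_equal(ctmbc:::swd_area_from_labels(all3), 100)
  # area is invariant under grid transposition
  expect_equal(ctmbc:::swd_area_from_labels(t(labs)),
               ctmbc:::swd_area_from_labels(labs))
})

test_that("majority vote breaks ties toward the more pathological state", {
  expect_identical(ctmbc:::majority_label(c("II", "III")), "III")
  expect_identical(ctmbc:::majority_label(c("I", "IV")), "IV")
  expect_identical(ctmbc:::majority_label(c("II", "II", "III")), "II")
  expect_identical(ctmbc:::majority_label(c("divergent", "I")), "I")
})

test_that("therapy comparison yields zero reduction for a null treatment", {
  cfg <- sim_config(duration = 15, transient = 5, n_repeats = 2, seed = 5)
  tab <- therapy_comparison(ctmbc_params(),
                            protocols = list(sham = stim_none()),
                            h7 = c(2.0, 2.5), h8 = c(9.2, 10.2),
                            config = cfg)
  expect_equal(tab$reduction[tab$scheme == "sham"], 0)
  expect_equal(tab$swd_area[tab$scheme == "sham"],
               tab$swd_area[tab$scheme == "none"])
  expect_equal(tab$rms_current[tab$scheme == "none"], 0)
})

test_that("therapy comparison validates grid compatibility", {
  cfg <- sim_config(duration = 15, transient = 5, n_repeats = 2, seed = 5)
  base <- sweep_2d(ctmbc_params(), h7 = c(2.0, 2.5), h8 = c(9.2, 10.2),
                   config = cfg)
  expect_error(
    therapy_comparison(ctmbc_params(), list(dbs = stim_protocol("dbs")),
                       h7 = c(1.5, 2.0), h8 = c(9.2, 10.2),
                       config = cfg, baseline_map = base),
    "grid")
})
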