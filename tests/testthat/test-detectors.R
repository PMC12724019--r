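test_that("band-pass keeps the analysis band and suppresses low frequencies", {
  t <- (0:9999) / 1000
  low <- sin(2 * pi * 10 * t)
  mid <- sin(2 * pi * 140 * t)
  expect_lt(stats::sd(bandpass(low)), 0.01 * stats::sd(low))
  expect_gt(stats::sd(bandpass(mid)), 0.90 * stats::sd(mid))
  expect_true(all(bandpass(numeric(1000)) == 0))
  expect_error(bandpass(mid, band = c(600, 800), fs = 1000), "Nyquist")
})

test_that("all four detectors return nothing on a zero signal and find injected bursts", {
  z <- numeric(30000)
  for (d in c("ste", "sll", "hil", "mni"))
    expect_equal(nrow(detect(z, d)), 0)

  bg <- generate_background(30, 1000, seed = 31)
  rms_ib <- stats::sd(bandpass(bg))
  y <- inject_event(bg, 15000, "oscillation", 140, 12 * rms_ib, 60)
  for (d in c("ste", "sll", "hil", "mni")) {
    ev <- detect(y, d)
    hit <- ev$onset < 15060 & ev$offset > 15000
    expect_true(any(hit), label = paste(d, "detects the burst"))
  }

  y2 <- inject_event(y, 17000, "oscillation", 200, 12 * rms_ib, 60)
  for (d in c("ste", "hil")) {
    ev <- detect(y2, d)
    near <- ev[ev$offset > 14500 & ev$onset < 17600, ]
    expect_equal(nrow(near), 2)
    expect_true(all(diff(near$onset) > 0))
  }
})

test_that("event merging unions nearby detections and never raises the count", {
  ev <- data.frame(onset = c(0, 55), offset = c(50, 100))
  m <- merge_events(ev, max_gap_ms = 10, fs = 1000)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$onset, m$offset), c(0, 100))
  ev2 <- data.frame(onset = c(0, 200), offset = c(50, 250))
  expect_identical(merge_events(ev2, 10, 1000), ev2)
  empty <- data.frame(onset = integer(0), offset = integer(0))
  expect_identical(merge_events(empty, 10, 1000), empty)
})

test_that("detection is deterministic and scale-invariant for SD-relative detectors", {
  ch <- burst_channel(seed = 37, snr_core = 5)
  xf <- bandpass(ch$signal)
  for (d in c("ste", "sll", "hil", "mni")) {
    e1 <- detect(xf, d, prefiltered = TRUE)
    e2 <- detect(xf, d, prefiltered = TRUE)
    expect_identical(e1, e2)
  }
  for (d in c("ste", "hil")) {
    e1 <- detect(xf, d, prefiltered = TRUE)
    e3 <- detect(3.7 * xf, d, prefiltered = TRUE)
    expect_identical(e1, e3)
  }
})

test_that("raising the primary threshold never increases the event count", {
  ch <- burst_channel(seed = 41, snr_core = 5)
  xf <- bandpass(ch$signal)
  primary <- list(ste = "threshold_sd", sll = "percentile",
                  hil = "threshold_sd", mni = "baseline_percentile")
  grids <- list(ste = c(3, 4, 5, 6, 8), sll = c(95, 97.5, 99, 99.9),
                hil = c(3, 4, 5, 6, 8), mni = c(99, 99.9, 99.99, 99.999))
  for (d in names(primary)) {
    counts <- vapply(grids[[d]], function(v) {
      p <- detector_defaults(d)
      p[[primary[[d]]]] <- v
      nrow(detect(xf, d, params = p, prefiltered = TRUE))
    }, 0)
    expect_true(all(diff(counts) <= 0),
                label = paste(d, "count monotone:",
                              paste(counts, collapse = ",")))
  }
})

test_that("STE, HIL and MNI stay quiet on event-free channels; SLL flags its design occupancy", {
  z <- generate_background(120, 1000, seed = 43)
  for (d in c("ste", "hil", "mni"))
    expect_lte(nrow(detect(z, d)) / 2, 5)
  # SLL thresholds at a fixed percentile, so suprathreshold occupancy is
  # bounded by its design fraction of samples
  sll <- detect(z, "sll")
  occ <- sum(sll$offset - sll$onset) / length(z)
  expect_lte(occ, 0.025 + 0.005)
})

test_that("short signals are rejected with the detector named", {
  expect_error(detect(numeric(100), "mni"), "mni")
})
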