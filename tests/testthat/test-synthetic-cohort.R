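test_that("background generation is reproducible, scalable, and 1/f-weighted", {
  x1 <- generate_background(1, 1000, seed = 7)
  x2 <- generate_background(1, 1000, seed = 7)
  expect_identical(x1, x2)
  expect_true(all(generate_background(1, 1000, seed = 1, scale = 0) == 0))
  expect_error(generate_background(-1, 1000), "positive")
  x <- generate_background(60, 1000, seed = 3)
  expect_lt(abs(mean(x)), 1e-8)
  spec <- Mod(stats::fft(x))^2
  f <- (seq_along(x) - 1) * 1000 / length(x)
  expect_lt(sum(spec[f >= 80 & f <= 500]), sum(spec[f >= 0.5 & f <= 30]))
})

test_that("injected events modify only their window and carry the stated spectra", {
  z <- numeric(4000)
  expect_identical(inject_event(z, 1000, "oscillation", 140, 0, 60), z)
  y <- inject_event(z, 1000, "oscillation", 140, 10, 60)
  expect_true(all(y[1:1000] == 0) && all(y[1062:4000] == 0))
  seg <- bandpass(y)[1001:1060]
  pk_f <- (which.max(Mod(stats::fft(c(seg, numeric(940))))[1:500]) - 1)
  expect_lt(abs(pk_f - 140), 5)
  expect_error(inject_event(z, 3980, "oscillation", 140, 10, 60), "epoch end")
  expect_error(inject_event(z, 100, "oscillation", 30, 10, 60), "80, 500")
})

test_that("spike events are spectrally broader than oscillations of equal amplitude", {
  z <- numeric(4000)
  zo <- inject_event(z, 2000, "oscillation", 140, 10, 60)
  set.seed(1)
  zs <- inject_event(z, 2000, "spike", 140, 10, 60)
  ev <- data.frame(onset = 2000, offset = 2060)
  eo <- event_morphology(zo, ev, 1000)$entropy
  es <- event_morphology(zs, ev, 1000)$entropy
  expect_gt(es, eo)
})

test_that("cohorts are reproducible and respect the configured prevalence", {
  cfg <- sim_config(n_patients = 3, channels_per_patient = 12, seed = 11)
  c1 <- generate_cohort(cfg, signals = FALSE)
  c2 <- generate_cohort(cfg, signals = FALSE)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$patients, c2$patients)
  s1 <- patient_signals(c1, "P002"); s2 <- patient_signals(c2, "P002")
  expect_identical(s1, s2)

  big <- generate_cohort(sim_config(n_patients = 42,
                                    channels_per_patient = 24, seed = 13),
                         signals = FALSE)
  frac <- mean(big$electrodes$soz)  # ~1000 channels
  expect_gt(frac, 0.14); expect_lt(frac, 0.20)
})

test_that("site-class rate parameters drive the empirical event rates", {
  flat <- sim_config(n_patients = 9, channels_per_patient = 24,
                     rate_params = c(soz = 1.5, spiking = 1.5,
                                     resected_other = 1.5,
                                     non_epileptic = 1.5),
                     seed = 17)
  co <- generate_cohort(flat, signals = FALSE)       # > 200 channels
  key <- paste(co$events$patient, co$events$channel)
  n_by_ch <- vapply(paste(co$electrodes$patient, co$electrodes$name),
                    function(k) sum(key == k), 0)
  soz_n <- n_by_ch[co$electrodes$soz]
  non_n <- n_by_ch[co$electrodes$site_class == "non_epileptic"]
  se <- sqrt(stats::var(soz_n) / length(soz_n) +
               stats::var(non_n) / length(non_n))
  expect_lt(abs(mean(soz_n) - mean(non_n)), 2 * se + 1e-9)

  # and under the default config SOZ channels are event-enriched
  def <- generate_cohort(sim_config(n_patients = 9,
                                    channels_per_patient = 24, seed = 19),
                         signals = FALSE)
  key <- paste(def$events$patient, def$events$channel)
  n_by_ch <- vapply(paste(def$electrodes$patient, def$electrodes$name),
                    function(k) sum(key == k), 0)
  expect_gt(mean(n_by_ch[def$electrodes$soz]),
            mean(n_by_ch[def$electrodes$site_class == "non_epileptic"]))
})

test_that("a zero outcome link yields coin-flip ILAE class 1 rates", {
  co <- generate_cohort(sim_config(n_patients = 500, outcome_link = 0,
                                   seed = 8), signals = FALSE)
  expect_gt(mean(co$patients$ilae_class1), 0.44)
  expect_lt(mean(co$patients$ilae_class1), 0.56)
})

test_that("ground-truth events are recoverable by band-pass plus envelope thresholding", {
  # oracle: events whose core in-band RMS is >= 5x background RMS must be
  # recovered by simple envelope thresholding at 3x background RMS
  set.seed(23)
  bg <- generate_background(120, 1000, seed = 23)
  rms_ib <- stats::sd(bandpass(bg))
  onsets <- seq(4000, 116000, by = 1500)
  kinds <- rep(c("oscillation", "spike", "spike_oscillation"),
               length.out = length(onsets))
  amp <- 5 * rms_ib / sqrt(3 / 16)
  y <- bg
  for (i in seq_along(onsets))
    y <- inject_event(y, onsets[i], kinds[i], 160, amp, 50)
  env <- abs(bandpass(y))
  env <- sqrt(hfatools:::moving_mean(env^2, 11))
  hits <- vapply(onsets, function(o)
    any(env[(o + 1):(o + 50)] > 3 * rms_ib), TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("cohort serialization writes EDF, TSV, CSV and JSON artifacts", {
  cfg <- sim_config(n_patients = 2, channels_per_patient = 8,
                    depth_shaft_contacts = 0, seed = 3)
  co <- generate_cohort(cfg, signals = TRUE)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "P001.edf")))
  expect_true(file.exists(file.path(dir, "P002_electrodes.tsv")))
  expect_true(file.exists(file.path(dir, "patients.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  el <- utils::read.delim(file.path(dir, "P001_electrodes.tsv"))
  expect_setequal(names(el), c("name", "kind", "shaft_id", "contact_index",
                               "hemisphere", "region", "soz", "spiking",
                               "resected", "excluded"))
  unlink(dir, recursive = TRUE)
})
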