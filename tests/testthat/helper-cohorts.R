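# Shared fixtures, built lazily and memoized for the whole test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Small cohort with signals, all four detectors: unit-scale checks.
small_cohort <- function() memo("small", function() {
  cfg <- sim_config(n_patients = 2, channels_per_patient = 16, seed = 5)
  generate_cohort(cfg, signals = FALSE)
})

small_features <- function() memo("small_feat", function() {
  cohort_features(small_cohort(), detectors = c("ste", "sll", "hil", "mni"))
})

# Derivation-scale cohort (79 patients, STE detector) shared by the
# model-recovery and pseudo-label acceptance checks.
ref_cohort <- function() memo("ref", function() {
  cfg <- sim_config(n_patients = 79, channels_per_patient = 16, seed = 20)
  generate_cohort(cfg, signals = FALSE)
})

ref_features_ste <- function() memo("ref_feat", function() {
  cohort_features(ref_cohort(), detectors = "ste")$features$ste
})

# A 120-s channel with events of every kind injected at a known SNR
# multiple of the in-band background RMS (peak amplitude ~ 2.4x the core
# RMS for a Hann-windowed burst).
burst_channel <- function(seed, snr_core = 5, spacing = 2000,
                          duration_ms = 60) {
  y <- generate_background(120, 1000, seed = seed)
  rms_ib <- stats::sd(bandpass(y))
  onsets <- seq(5000, 115000, by = spacing)
  kinds <- rep(c("oscillation", "spike", "spike_oscillation"),
               length.out = length(onsets))
  set.seed(seed * 2 + 1)
  amp <- snr_core * rms_ib / sqrt(3 / 16)  # Hann-burst core RMS -> peak
  for (i in seq_along(onsets))
    y <- inject_event(y, onsets[i], kinds[i], 140, amp, duration_ms)
  list(signal = y, onsets = onsets, kinds = kinds,
       duration = round(duration_ms), rms_ib = rms_ib, amp = amp)
}

recall_of <- function(events, onsets, duration) {
  mean(vapply(onsets, function(o)
    any(events$onset < o + duration & events$offset > o), TRUE))
}

# Exhaustive pair-counting AUROC oracle (half credit for ties).
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Per-patient paired medians of one electrode feature at SOZ vs
# non-epileptic sites (Table-1-style contrast).
paired_patient_medians <- function(tbl, feature) {
  pats <- unique(tbl$patient)
  soz <- non <- rep(NA_real_, length(pats))
  for (i in seq_along(pats)) {
    sub <- tbl[tbl$patient == pats[i], ]
    if (any(sub$label == 1, na.rm = TRUE))
      soz[i] <- stats::median(sub[[feature]][sub$label == 1], na.rm = TRUE)
    if (any(sub$label == 0, na.rm = TRUE))
      non[i] <- stats::median(sub[[feature]][sub$label == 0], na.rm = TRUE)
  }
  ok <- !is.na(soz) & !is.na(non)
  list(soz = soz[ok], non = non[ok])
}

# True-rate biomarker difference per patient from cohort ground truth.
true_rate_differences <- function(cohort) {
  vapply(cohort$patients$patient, function(pid) {
    el <- cohort$electrodes[cohort$electrodes$patient == pid &
                              !cohort$electrodes$excluded, ]
    suppressWarnings(biomarker_difference(el$true_rate, el$resected))
  }, 0)
}
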