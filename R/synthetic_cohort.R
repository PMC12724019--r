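# Synthetic multi-patient iEEG cohorts with ground-truth HFA events, SOZ /
# spiking / resection labels, clinical covariates and ILAE outcomes, so the
# whole detection -> features -> model -> outcome pipeline is testable
# without patient recordings.

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: non-REM epochs at
#' 1000 Hz, 16.8% SOZ-site prevalence, three HFA morphological classes
#' (narrow-band oscillation, broadband spike, spike-oscillation complex),
#' and SOZ sites with higher event rate, amplitude, and spike-oscillation
#' share than non-epileptic sites. Event rates and amplitudes are given per
#' site class; the class mix row-normalizes over the three event kinds.
#'
#' @param n_patients Number of patients.
#' @param channels_per_patient Electrode contacts per patient.
#' @param soz_prevalence Expected SOZ site fraction (default 0.168).
#' @param epoch_minutes Epoch length, 5 or 20 minutes (default 5).
#' @param sampling_rate Hz (default 1000).
#' @param rate_params Events/min by site class.
#' @param amplitude_params Mean event amplitude (uV) by site class.
#' @param event_class_mix Probability over (oscillation, spike,
#'   spike_oscillation) by site class.
#' @param freq_params Center-frequency range (Hz) for oscillatory kinds.
#' @param duration_params Duration range (ms) by event kind.
#' @param background_rms Broadband pink-noise RMS (uV).
#' @param slow_amp Slow-wave (0.5-4 Hz) amplitude (uV).
#' @param spiking_prob,excluded_prob Per-channel probabilities of the
#'   spiking label and of artifact exclusion.
#' @param depth_shaft_contacts Contacts on the single depth shaft per
#'   patient (0 disables depth electrodes); >= 4 when present.
#' @param outcome_link Coefficient beta of the logistic outcome rule
#'   p(ILAE 1) = plogis(intercept + beta * true biomarker difference).
#' @param outcome_intercept Intercept of the outcome rule (default 0).
#' @param seed Integer master seed.
#' @return Validated config list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 10,
                       channels_per_patient = 24,
                       soz_prevalence = 0.168,
                       epoch_minutes = 5,
                       sampling_rate = 1000,
                       rate_params = c(soz = 3.0, spiking = 1.5,
                                       resected_other = 0.8,
                                       non_epileptic = 0.6),
                       amplitude_params = c(soz = 24, spiking = 19,
                                            resected_other = 17,
                                            non_epileptic = 16),
                       event_class_mix = rbind(
                         soz = c(oscillation = 0.30, spike = 0.30,
                                 spike_oscillation = 0.40),
                         spiking = c(0.35, 0.45, 0.20),
                         resected_other = c(0.50, 0.35, 0.15),
                         non_epileptic = c(0.55, 0.35, 0.10)),
                       freq_params = c(90, 250),
                       duration_params = rbind(
                         oscillation = c(20, 80),
                         spike = c(40, 80),
                         spike_oscillation = c(40, 80)),
                       background_rms = 5,
                       slow_amp = 20,
                       spiking_prob = 0.10,
                       excluded_prob = 0.04,
                       depth_shaft_contacts = 6,
                       outcome_link = 1.5,
                       outcome_intercept = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1, cfg$channels_per_patient >= 4,
            cfg$soz_prevalence > 0, cfg$soz_prevalence < 1,
            cfg$epoch_minutes %in% c(5, 20),
            cfg$sampling_rate >= 2 * max(cfg$freq_params),
            all(abs(rowSums(cfg$event_class_mix) - 1) < 1e-8),
            cfg$depth_shaft_contacts == 0 || cfg$depth_shaft_contacts >= 4)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate non-REM-like background iEEG
#'
#' Pink noise (power spectral density ~ 1/f, so power decreases with
#' frequency above the slow-wave range) plus one 0.5-4 Hz slow-wave
#' component, zero-mean.
#'
#' @param duration_s Epoch length in seconds (> 0).
#' @param fs Sampling rate in Hz (> 0).
#' @param seed Optional integer seed (reproducible when fixed).
#' @param scale Pink-noise RMS in uV; 0 yields an all-zero signal.
#' @param slow_amp Slow-wave amplitude in uV.
#' @return Numeric signal vector of length `duration_s * fs`.
#' @export
generate_background <- function(duration_s, fs, seed = NULL, scale = 5,
                                slow_amp = 20) {
  if (duration_s <= 0 || fs <= 0)
    stop("duration and sampling rate must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- round(duration_s * fs)
  if (scale == 0) return(numeric(n))
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  freq <- c(0, seq_len(n - 1)) * fs / n
  freq <- pmin(freq, fs - freq)          # two-sided frequency axis
  wt <- 1 / sqrt(pmax(freq, 0.5))        # PSD ~ 1/f, floored below 0.5 Hz
  wt[1] <- 0                              # zero mean
  x <- Re(stats::fft(f * wt, inverse = TRUE) / n)
  if (stats::sd(x) > 0) x <- x / stats::sd(x) * scale
  if (slow_amp > 0) {
    sw_f <- stats::runif(1, 0.5, 4)
    sw_ph <- stats::runif(1, 0, 2 * pi)
    x <- x + slow_amp * sin(2 * pi * sw_f * seq_len(n) / fs + sw_ph)
  }
  x - mean(x)
}

#' Inject one HFA event into a signal
#'
#' Oscillation: Hann-windowed sinusoid at the center frequency. Spike:
#' sharp biphasic (derivative-of-Gaussian) transient plus a Hann-enveloped
#' broadband (80-500 Hz) noise burst spanning the event, emulating the
#' high-frequency augmentation that rides on interictal spikes.
#' Spike-oscillation complex: both superimposed. The signal is modified
#' only within the event window.
#'
#' @param x Signal vector.
#' @param onset 0-based onset sample.
#' @param kind "oscillation", "spike", or "spike_oscillation".
#' @param center_freq Center frequency (Hz) for oscillatory kinds, in
#'   \[80, 500\].
#' @param amplitude Peak amplitude (uV); 0 leaves the signal unchanged.
#' @param duration_ms Event duration (ms).
#' @param fs Sampling rate (Hz).
#' @return The signal with the event added.
#' @export
inject_event <- function(x, onset, kind, center_freq, amplitude,
                         duration_ms, fs = 1000) {
  kind <- match.arg(kind, c("oscillation", "spike", "spike_oscillation"))
  n_ev <- round(duration_ms / 1000 * fs)
  if (onset < 0 || onset + n_ev > length(x))
    stop("event extends past the epoch end")
  if (kind != "spike" &&
      (center_freq < 80 || center_freq > 500))
    stop("oscillation center frequency must lie in [80, 500] Hz")
  if (amplitude == 0) return(x)
  idx <- onset + seq_len(n_ev)            # 1-based slice for 0-based onset
  t <- (seq_len(n_ev) - 1) / fs
  ev <- numeric(n_ev)
  if (kind %in% c("oscillation", "spike_oscillation")) {
    hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_ev) - 1) / (n_ev - 1))
    ev <- ev + amplitude * hann * sin(2 * pi * center_freq * t)
  }
  if (kind %in% c("spike", "spike_oscillation")) {
    hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n_ev) - 1) / (n_ev - 1))
    sigma <- 0.0015                        # 1.5 ms: content across 80-500 Hz
    tc <- t - t[n_ev] / 2
    g <- -tc / sigma * exp(0.5 - tc^2 / (2 * sigma^2))
    ev <- ev + amplitude * g / max(abs(g))
    # broadband high-frequency augmentation across the event
    noise <- stats::rnorm(n_ev)
    f <- (seq_len(n_ev) - 1) / n_ev * fs
    f <- pmin(f, fs - f)
    mask <- as.numeric(f >= 80 & f <= min(500, fs / 2))
    hf <- Re(stats::fft(stats::fft(noise) * mask, inverse = TRUE) / n_ev)
    # match the Hann-windowed sinusoid's RMS for the same amplitude value
    if (stats::sd(hf) > 0) hf <- hf / stats::sd(hf) * sqrt(1 / 2)
    ev <- ev + amplitude * hann * hf
  }
  x[idx] <- x[idx] + ev
  x
}

draw_channel_events <- function(n_samples, fs, rate_per_min, class_probs,
                                amp_mean, freq_range, duration_params) {
  minutes <- n_samples / fs / 60
  n_ev <- stats::rpois(1, rate_per_min * minutes)
  if (n_ev == 0)
    return(data.frame(onset = integer(0), offset = integer(0),
                      class = character(0), center_freq = numeric(0),
                      amplitude = numeric(0)))
  kinds <- sample(rownames(duration_params), n_ev, replace = TRUE,
                  prob = class_probs)
  dur_ms <- vapply(kinds, function(k)
    stats::runif(1, duration_params[k, 1], duration_params[k, 2]), 0)
  dur_n <- round(dur_ms / 1000 * fs)
  # event onsets spaced at least 300 ms apart (greedy thinning)
  cand <- sort(sample.int(n_samples - max(dur_n) - 1L, n_ev))
  keep <- rep(TRUE, n_ev)
  last <- -Inf
  for (i in seq_len(n_ev)) {
    if (cand[i] - last < 0.3 * fs) keep[i] <- FALSE else last <- cand[i]
  }
  onset <- cand[keep]; kinds <- kinds[keep]; dur_n <- dur_n[keep]
  n_ev <- length(onset)
  data.frame(
    onset = onset, offset = onset + dur_n, class = kinds,
    center_freq = stats::runif(n_ev, freq_range[1], freq_range[2]),
    amplitude = pmax(5, stats::rnorm(n_ev, amp_mean, 0.2 * amp_mean)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic iEEG cohort
#'
#' Draws per-patient electrode layouts (subdural grid plus an optional
#' depth shaft), site classes at the configured SOZ prevalence, ground-truth
#' events per channel, a resection mask, clinical covariates, and ILAE
#' outcomes from the logistic link on the true biomarker difference
#' (computed from ground-truth event rates over resected vs preserved
#' contacts).
#'
#' @param cfg A [sim_config].
#' @param signals Synthesize full signal matrices (default `TRUE`); set
#'   `FALSE` for metadata-and-ground-truth-only cohorts used in
#'   patient-level statistical experiments.
#' @return List with `patients` (clinical table), `electrodes` (channel
#'   metadata), `events` (ground-truth event table), and `recordings`
#'   (named list of samples x channels matrices, or `NULL`s).
#' @export
generate_cohort <- function(cfg = sim_config(), signals = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(cfg$seed))
  fs <- cfg$sampling_rate
  n_samp <- round(cfg$epoch_minutes * 60 * fs)
  site_classes <- c("soz", "spiking", "resected_other", "non_epileptic")

  patients <- list(); electrodes <- list(); events <- list()
  recordings <- stats::setNames(vector("list", cfg$n_patients),
                                sprintf("P%03d", seq_len(cfg$n_patients)))
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%03d", p)
    n_ch <- cfg$channels_per_patient
    n_depth <- if (cfg$depth_shaft_contacts >= 4 &&
                   n_ch - cfg$depth_shaft_contacts >= 4)
      cfg$depth_shaft_contacts else 0L
    n_sub <- n_ch - n_depth
    name <- c(sprintf("G%02d", seq_len(n_sub)),
              if (n_depth) sprintf("D%02d", seq_len(n_depth)))
    kind <- c(rep("subdural", n_sub), rep("depth", n_depth))
    shaft_id <- c(rep(NA_character_, n_sub), rep("S1", n_depth))
    contact_index <- c(rep(NA_integer_, n_sub),
                       if (n_depth) seq_len(n_depth))
    region <- sample(region_levels(), n_ch, replace = TRUE)
    hemisphere <- substr(region, 1, 1)

    is_soz <- stats::runif(n_ch) < cfg$soz_prevalence
    is_spiking <- !is_soz & stats::runif(n_ch) < cfg$spiking_prob
    excluded <- !is_soz & stats::runif(n_ch) < cfg$excluded_prob

    # resection: quality-weighted removal of SOZ, some spiking, few others
    quality <- stats::rbeta(1, 2.5, 1.5)
    resected <- (is_soz & stats::runif(n_ch) < quality) |
      (is_spiking & stats::runif(n_ch) < 0.5 * quality) |
      (!is_soz & !is_spiking & stats::runif(n_ch) < 0.05)
    site <- ifelse(is_soz, "soz",
                   ifelse(is_spiking, "spiking",
                          ifelse(resected, "resected_other",
                                 "non_epileptic")))
    true_rate <- unname(cfg$rate_params[site])

    el <- data.frame(
      patient = pid, name = name, kind = kind, shaft_id = shaft_id,
      contact_index = contact_index, hemisphere = hemisphere,
      region = region, soz = is_soz, spiking = is_spiking,
      resected = resected, excluded = excluded, site_class = site,
      true_rate = true_rate, stringsAsFactors = FALSE)

    ev_p <- list()
    for (j in seq_len(n_ch)) {
      ev <- draw_channel_events(
        n_samp, fs, cfg$rate_params[[site[j]]],
        cfg$event_class_mix[site[j], ],
        cfg$amplitude_params[[site[j]]],
        cfg$freq_params, cfg$duration_params)
      if (nrow(ev)) {
        ev$patient <- pid; ev$channel <- name[j]
        ev_p[[length(ev_p) + 1L]] <- ev
      }
    }

    # outcome from the true-rate biomarker difference
    ok <- !excluded
    d <- if (any(resected & ok) && any(!resected & ok))
      mean(true_rate[resected & ok]) - mean(true_rate[!resected & ok])
    else 0
    p_ilae1 <- stats::plogis(cfg$outcome_intercept + cfg$outcome_link * d)
    ilae1 <- stats::runif(1) < p_ilae1
    patients[[p]] <- data.frame(
      patient = pid,
      age = round(stats::runif(1, 4, 21), 1),
      sex = sample(c("F", "M"), 1),
      daily_seizures = stats::runif(1) < 0.4,
      n_asms = sample(1:4, 1),
      hemisphere = sample(c("L", "R"), 1),
      mri_lesion = stats::runif(1) < 0.6,
      habitual_seizures_captured = stats::runif(1) < 0.9,
      soz_incompletely_removed = any(is_soz & !resected),
      extratemporal_resection =
        any(resected & !grepl("temporal", region)),
      resection_extent = mean(resected),
      etiology = sample(c("non-lesional", "tumor", "dysplasia",
                          "encephalomalacia"), 1,
                        prob = c(0.3, 0.15, 0.35, 0.2)),
      ilae_class1 = ilae1,
      true_diff = d,
      epoch_minutes = cfg$epoch_minutes,
      stringsAsFactors = FALSE)
    electrodes[[p]] <- el
    if (length(ev_p)) events[[p]] <- do.call(rbind, ev_p)
  }
  cohort <- list(
    cfg = cfg,
    patients = do.call(rbind, patients),
    electrodes = do.call(rbind, electrodes),
    events = if (length(events)) do.call(rbind, events) else
      data.frame(onset = integer(0), offset = integer(0),
                 class = character(0), center_freq = numeric(0),
                 amplitude = numeric(0), patient = character(0),
                 channel = character(0)),
    recordings = recordings)
  if (signals)
    for (pid in names(recordings))
      cohort$recordings[[pid]] <- patient_signals(cohort, pid)
  cohort
}

#' Synthesize one patient's signal matrix from cohort ground truth
#'
#' Backgrounds are drawn from a per-patient seed derived from the master
#' seed, then the patient's ground-truth events are injected, so signals
#' are reproducible patient-by-patient without holding the whole cohort in
#' memory.
#'
#' @param cohort Result of [generate_cohort] (any `signals` setting).
#' @param pid Patient id (e.g. `"P001"`).
#' @return Samples x channels matrix (uV).
#' @export
patient_signals <- function(cohort, pid) {
  cfg <- cohort$cfg
  fs <- cfg$sampling_rate
  el <- cohort$electrodes[cohort$electrodes$patient == pid, , drop = FALSE]
  if (!nrow(el)) stop("unknown patient ", pid)
  p_idx <- match(pid, unique(cohort$electrodes$patient))
  n_samp <- round(cfg$epoch_minutes * 60 * fs)
  set.seed((as.integer(cfg$seed) + 7919L * p_idx) %% .Machine$integer.max)
  sig <- matrix(0, n_samp, nrow(el), dimnames = list(NULL, el$name))
  ev_p <- cohort$events[cohort$events$patient == pid, , drop = FALSE]
  for (j in seq_len(nrow(el))) {
    x <- generate_background(cfg$epoch_minutes * 60, fs,
                             scale = cfg$background_rms,
                             slow_amp = cfg$slow_amp)
    ev <- ev_p[ev_p$channel == el$name[j], , drop = FALSE]
    for (e in seq_len(nrow(ev)))
      x <- inject_event(x, ev$onset[e], ev$class[e], ev$center_freq[e],
                        ev$amplitude[e],
                        (ev$offset[e] - ev$onset[e]) / fs * 1000, fs)
    sig[, j] <- x
  }
  sig
}

#' Write a cohort to disk in its interchange formats
#'
#' Signals as one EDF file per patient, per-patient electrode tables as
#' TSV, the cohort patient table as CSV, and ground truth as JSON.
#'
#' @param cohort Result of [generate_cohort].
#' @param dir Output directory (created if missing).
#' @param fs Sampling rate used for the EDF headers.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, fs = 1000) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(cohort$recordings)) {
    sig <- cohort$recordings[[pid]]
    if (!is.null(sig))
      write_edf(file.path(dir, paste0(pid, ".edf")), sig, fs = fs)
    el <- cohort$electrodes[cohort$electrodes$patient == pid, ]
    utils::write.table(
      el[, c("name", "kind", "shaft_id", "contact_index", "hemisphere",
             "region", "soz", "spiking", "resected", "excluded")],
      file.path(dir, paste0(pid, "_electrodes.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$events, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}
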