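# Per-event morphology: multitaper time-frequency power, peak frequency,
# normalized spectral entropy, and per-electrode aggregation into the
# seven-feature model input rows.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the tridiagonal eigenproblem formulation; tapers are
#' unit-energy and sign-standardized (first taper positive mean).
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers (k <= 2*nw - 1 recommended).
#' @return n x k matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  stopifnot(n >= 2, k >= 1)
  w <- nw / n
  t_idx <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  diag_off <- t_idx[-1] * (n - t_idx[-1]) / 2
  m <- diag(diag_main)
  m[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- diag_off
  m[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- diag_off
  e <- eigen(m, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (j %% 2 == 1 && sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
    if (j %% 2 == 0 && tap[2, j] < 0) tap[, j] <- -tap[, j]
  }
  tap
}

.tf_cache <- new.env(parent = emptyenv())

cached_tapers <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  if (is.null(.tf_cache[[key]]))
    .tf_cache[[key]] <- dpss_tapers(n, nw, k)
  .tf_cache[[key]]
}

#' Default time-frequency configuration
#'
#' 200-ms windows, 5-Hz frequency bins spanning 80-500 Hz, 1-ms slide;
#' 3 Slepian tapers at time-bandwidth product 2. The 5-Hz bin spacing is
#' the natural FFT resolution of a 200-ms window at 1000 Hz, so no
#' zero-padding is applied.
#'
#' @param window_ms Analysis window length (ms).
#' @param step_ms Slide between successive windows (ms).
#' @param band Analysis band in Hz (inclusive bin centers).
#' @param nw,k Multitaper time-bandwidth product and taper count.
#' @return Config list.
#' @export
tf_config <- function(window_ms = 200, step_ms = 1, band = c(80, 500),
                      nw = 2, k = 3) {
  list(window_ms = window_ms, step_ms = step_ms, band = band, nw = nw, k = k)
}

#' Multitaper time-frequency map around one event
#'
#' Power (uV^2 scale) on a (frequency bin x time) grid covering the event
#' extent, estimated with Slepian tapers over a sliding window centered on
#' each time step. The signal is reflection-padded so events near the epoch
#' edge still get full windows; events with less context than half a window
#' on either side of the whole epoch are flagged.
#'
#' @param x Numeric signal vector (one montage channel, unfiltered).
#' @param onset,offset Event bounds as 0-based sample indices, half-open.
#' @param fs Sampling rate (Hz).
#' @param cfg Configuration from [tf_config].
#' @return List: `power` (freq x time matrix), `freqs` (bin centers, Hz),
#'   `times` (sample index of each column), `flagged` (logical).
#' @export
multitaper_tf <- function(x, onset, offset, fs, cfg = tf_config()) {
  stopifnot(offset > onset, onset >= 0)
  n_win <- round(cfg$window_ms / 1000 * fs)
  half <- n_win %/% 2
  step <- max(1L, round(cfg$step_ms / 1000 * fs))
  centers <- seq(from = onset, to = offset - 1, by = step)
  flagged <- length(x) < n_win
  # reflection padding
  pad <- half + 1L
  xp <- c(rev(x[seq_len(min(pad, length(x)))]), x,
          rev(x[seq(length(x) - min(pad, length(x)) + 1L, length(x))]))
  off0 <- min(pad, length(x))  # index shift into xp

  tapers <- cached_tapers(n_win, cfg$nw, cfg$k)
  df <- fs / n_win
  k_lo <- ceiling(cfg$band[1] / df)
  k_hi <- floor(min(cfg$band[2], fs / 2) / df)
  freqs <- (k_lo:k_hi) * df

  offs <- seq_len(n_win) - half - 1L
  idx <- outer(offs, centers + 1L + off0, "+")
  idx[idx < 1L] <- 1L
  idx[idx > length(xp)] <- length(xp)
  seg <- matrix(xp[idx], nrow = n_win)

  pow <- 0
  for (j in seq_len(cfg$k)) {
    ft <- stats::mvfft(seg * tapers[, j])
    pow <- pow + (Mod(ft[k_lo:k_hi + 1L, , drop = FALSE])^2)
  }
  pow <- pow / cfg$k * (2 / n_win)  # one-sided power scale
  dimnames(pow) <- NULL
  list(power = matrix(pow, nrow = length(freqs)), freqs = freqs,
       times = centers, flagged = flagged)
}

#' Maximum spectral power and its frequency within an event
#'
#' Maximum over all time-frequency cells whose time index lies within the
#' event; the peak frequency is the center of the argmax bin, with ties
#' broken toward the lower frequency bin.
#'
#' @param tf Time-frequency map from [multitaper_tf].
#' @param onset,offset Event bounds (0-based samples, half-open).
#' @return List with `max_power` and `peak_freq` (Hz).
#' @export
max_power_and_peak_freq <- function(tf, onset, offset) {
  keep <- tf$times >= onset & tf$times < offset
  if (!any(keep)) stop("empty event bounds for time-frequency map")
  p <- tf$power[, keep, drop = FALSE]
  mx <- max(p)
  # which.max scans column-major, so the first hit is the lowest frequency
  # bin at the earliest time; restrict to rows for the frequency tie rule
  row_max <- apply(p, 1, max)
  f_idx <- which(row_max >= mx)[1]
  list(max_power = mx, peak_freq = tf$freqs[f_idx])
}

#' Normalized spectral entropy of an event spectrum
#'
#' Shannon entropy of the normalized power distribution over N frequency
#' bins, H = -sum P(f_i) log2(P(f_i) + eps), divided by the maximum
#' attainable entropy log2(N). Ranges from 0 (all power in one bin) to 1
#' (flat spectrum), up to the small eps correction.
#'
#' @param spectrum Nonnegative power per frequency bin (N >= 2); typically
#'   the time-averaged power over the event's extent.
#' @param eps Small constant guarding log2(0) (default 1e-12).
#' @return H_norm in \[0, 1\], or `NA` (flagged) for an all-zero spectrum.
#' @export
normalized_entropy <- function(spectrum, eps = 1e-12) {
  n <- length(spectrum)
  stopifnot(n >= 2, all(spectrum >= 0))
  tot <- sum(spectrum)
  if (tot == 0) return(NA_real_)
  p <- spectrum / tot
  h <- -sum(p * log2(p + eps))
  max(0, h / log2(n))
}

#' Morphology features for a list of detected events on one channel
#'
#' Runs the multitaper analysis per event and extracts duration, maximum
#' spectral power, peak frequency, and normalized spectral entropy (from
#' the event's time-averaged spectrum).
#'
#' @param x Montaged (unfiltered) signal vector.
#' @param events `data.frame` with columns `onset`, `offset` (0-based
#'   samples, half-open).
#' @param fs Sampling rate (Hz).
#' @param cfg Time-frequency configuration ([tf_config]).
#' @return The events `data.frame` extended with `duration_ms`,
#'   `max_power_uv2`, `peak_freq_hz`, `entropy`.
#' @export
event_morphology <- function(x, events, fs, cfg = tf_config()) {
  n <- nrow(events)
  dur <- (events$offset - events$onset) / fs * 1000
  mp <- pf <- en <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tf <- multitaper_tf(x, events$onset[i], events$offset[i], fs, cfg)
    if (tf$flagged) next
    pk <- max_power_and_peak_freq(tf, events$onset[i], events$offset[i])
    mp[i] <- pk$max_power
    pf[i] <- pk$peak_freq
    en[i] <- normalized_entropy(rowMeans(tf$power))
  }
  cbind(events, data.frame(duration_ms = dur, max_power_uv2 = mp,
                           peak_freq_hz = pf, entropy = en))
}

#' Aggregate one electrode's events into a model feature row
#'
#' Rate is events per minute; morphology features are summarized by their
#' median over the electrode's events (configurable to the mean).
#' Electrodes with zero events get rate 0 and missing morphology, which the
#' downstream tree model handles natively.
#'
#' @param events Events-with-morphology `data.frame` for one electrode (may
#'   have zero rows).
#' @param epoch_minutes Recording epoch length in minutes.
#' @param region Anatomical region label (one of the 12-level vocabulary).
#' @param age Patient age in years.
#' @param agg Aggregator for morphology: "median" (default) or "mean".
#' @return One-row `data.frame` with the seven model features.
#' @export
aggregate_electrode <- function(events, epoch_minutes, region, age,
                                agg = c("median", "mean")) {
  stopifnot(epoch_minutes > 0)
  agg <- match.arg(agg)
  f <- if (agg == "median") stats::median else mean
  summ <- function(v) if (nrow(events) == 0 || all(is.na(v))) NA_real_
    else f(v, na.rm = TRUE)
  data.frame(
    rate = nrow(events) / epoch_minutes,
    median_duration = summ(events$duration_ms),
    median_power = summ(events$max_power_uv2),
    median_freq = summ(events$peak_freq_hz),
    median_entropy = summ(events$entropy),
    region = region, age = age,
    stringsAsFactors = FALSE)
}

#' The fixed 12-level anatomical region vocabulary
#' @return Character vector of region labels.
#' @export
region_levels <- function() {
  as.vector(outer(c("L", "R"),
                  c("frontal", "central", "parietal", "occipital",
                    "temporal", "insular"),
                  function(h, r) paste(h, r, sep = "_")))
}

#' Build per-detector cohort feature tables
#'
#' One row per eligible electrode and detector. Training tables keep only
#' SOZ and non-epileptic electrodes (spiking-only and resected-other sites
#' are excluded); with `training = FALSE` all included electrodes are kept
#' and labeled NA where ineligible.
#'
#' @param events Cohort events-with-morphology `data.frame` with columns
#'   `patient`, `channel` (electrode contact name), `detector`, and the
#'   morphology columns from [event_morphology].
#' @param electrodes Cohort electrode table: `patient`, `name`, `region`,
#'   `soz`, `spiking`, `resected`, `excluded`.
#' @param patients Patient table with `patient`, `age`, `epoch_minutes`.
#' @param training Keep only SOZ / non-epileptic rows (default `TRUE`).
#' @param agg Morphology aggregator passed to [aggregate_electrode].
#' @return Named list of `data.frame`s, one per detector present, each with
#'   the seven features plus `patient`, `channel`, `label` (1 = SOZ).
#' @export
cohort_feature_table <- function(events, electrodes, patients,
                                 training = TRUE, agg = "median") {
  el <- electrodes[!electrodes$excluded, , drop = FALSE]
  non_epileptic <- !el$soz & !el$spiking & !el$resected
  el$label <- ifelse(el$soz, 1L, ifelse(non_epileptic, 0L, NA_integer_))
  if (training) el <- el[!is.na(el$label), , drop = FALSE]
  detectors <- sort(unique(events$detector))
  if (!length(detectors)) detectors <- "none"
  out <- list()
  for (d in detectors) {
    ev_d <- events[events$detector == d, , drop = FALSE]
    rows <- vector("list", nrow(el))
    for (i in seq_len(nrow(el))) {
      pat <- el$patient[i]; ch <- el$name[i]
      prow <- patients[patients$patient == pat, , drop = FALSE]
      if (nrow(prow) != 1L)
        stop("no patient metadata for channel ", ch, " (patient ", pat, ")")
      ev_i <- ev_d[ev_d$patient == pat & ev_d$channel == ch, , drop = FALSE]
      r <- aggregate_electrode(ev_i, prow$epoch_minutes, el$region[i],
                               prow$age, agg = agg)
      r$patient <- pat; r$channel <- ch; r$label <- el$label[i]
      rows[[i]] <- r
    }
    out[[d]] <- do.call(rbind, rows)
  }
  out
}
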