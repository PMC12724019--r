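# Automatic HFA detectors (STE, SLL, HIL, MNI) over 80-500 Hz band-passed
# iEEG. Sample indexing is 0-based with half-open [onset, offset) intervals.
# Numeric defaults live in inst/extdata/detector_defaults.yaml, following
# the original detector publications.

#' Zero-phase FIR band-pass filter
#'
#' Forward-backward filtering with a Hamming-window FIR design so detected
#' event timing is not shifted; the upper edge is clipped below Nyquist.
#'
#' @param x Signal vector.
#' @param band Length-2 Hz interval (default c(80, 500)).
#' @param fs Sampling rate (Hz).
#' @param order FIR order (default 128).
#' @param method `"fft"` (default) applies the FIR's forward-backward
#'   magnitude response in the frequency domain (fast for long epochs);
#'   `"filtfilt"` runs time-domain forward-backward filtering.
#' @return Filtered signal of the same length.
#' @export
bandpass <- function(x, band = c(80, 500), fs = 1000, order = 128,
                     method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  nyq <- fs / 2
  hi <- min(band[2], 0.98 * nyq)
  lo <- band[1]
  if (lo <= 0 || lo >= hi || hi >= nyq)
    stop("band edges must satisfy 0 < low < high < Nyquist after clipping")
  h <- signal::fir1(order, c(lo, hi) / nyq, type = "pass")
  if (method == "filtfilt") return(as.numeric(signal::filtfilt(h, x)))
  n <- length(x)
  hr <- Mod(stats::fft(c(h, numeric(n - length(h)))))^2  # |H|^2: two passes
  Re(stats::fft(stats::fft(x) * hr, inverse = TRUE) / n)
}

moving_mean <- function(x, w) {
  # centered moving average, edges renormalized by the valid count
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) - half + w - 1L, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

runs_above <- function(mask) {
  # contiguous TRUE runs -> 0-based half-open (onset, offset) data.frame
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(onset = starts[keep] - 1L, offset = ends[keep])
}

#' Merge adjacent detections separated by less than a gap
#'
#' Events whose gap is smaller than `max_gap_ms` are unioned; the count
#' never increases.
#'
#' @param events `data.frame` with `onset`, `offset` (0-based, half-open),
#'   sorted by onset.
#' @param max_gap_ms Maximum gap to bridge (ms).
#' @param fs Sampling rate (Hz).
#' @return Merged events `data.frame`.
#' @export
merge_events <- function(events, max_gap_ms = 10, fs = 1000) {
  if (nrow(events) <= 1L) return(events)
  gap <- max_gap_ms / 1000 * fs
  on <- events$onset; off <- events$offset
  keep_on <- on[1]; out_on <- c(); out_off <- c()
  cur_off <- off[1]
  for (i in seq_len(nrow(events))[-1]) {
    if (on[i] - cur_off < gap) {
      cur_off <- max(cur_off, off[i])
    } else {
      out_on <- c(out_on, keep_on); out_off <- c(out_off, cur_off)
      keep_on <- on[i]; cur_off <- off[i]
    }
  }
  data.frame(onset = c(out_on, keep_on), offset = c(out_off, cur_off))
}

filter_min_duration <- function(events, min_ms, fs) {
  events[(events$offset - events$onset) >= min_ms / 1000 * fs, ,
         drop = FALSE]
}

#' Default detector parameters
#'
#' Reads the versioned YAML defaults shipped with the package (per-detector
#' thresholds, window lengths, minimum durations), following the original
#' detector publications.
#'
#' @param detector One of "ste", "sll", "hil", "mni", or NULL for all.
#' @return Named parameter list.
#' @export
detector_defaults <- function(detector = NULL) {
  path <- system.file("extdata", "detector_defaults.yaml",
                      package = "hfatools")
  cfg <- yaml::read_yaml(path)
  if (is.null(detector)) cfg else cfg[[tolower(detector)]]
}

detect_ste <- function(xf, fs, p) {
  w <- max(3L, round(p$rms_window_ms / 1000 * fs))
  rms <- sqrt(moving_mean(xf^2, w))
  thr <- mean(rms) + p$threshold_sd * stats::sd(rms)
  ev <- runs_above(rms > thr)
  ev <- merge_events(ev, p$merge_gap_ms, fs)
  ev <- filter_min_duration(ev, p$min_duration_ms, fs)
  if (!nrow(ev)) return(ev)
  # secondary criterion: enough rectified peaks above a lower threshold,
  # counted in a short context window around the suprathreshold run
  rect <- abs(xf)
  peak_thr <- mean(rect) + p$peak_threshold_sd * stats::sd(rect)
  is_peak <- c(FALSE, diff(sign(diff(rect))) < 0, FALSE) & rect > peak_thr
  cum_pk <- cumsum(is_peak)
  ctx <- round((p$peak_context_ms %||% 20) / 1000 * fs)
  lo <- pmax(ev$onset - ctx, 1L)
  hi <- pmin(ev$offset + ctx, length(xf))
  n_pk <- cum_pk[hi] - cum_pk[lo]
  ev[n_pk >= p$min_peaks, , drop = FALSE]
}

detect_sll <- function(xf, fs, p) {
  w <- max(3L, round(p$window_ms / 1000 * fs))
  ll <- moving_mean(c(abs(diff(xf)), 0), w)
  thr <- stats::quantile(ll, p$percentile / 100, names = FALSE)
  ev <- runs_above(ll > thr)
  ev <- merge_events(ev, p$merge_gap_ms, fs)
  filter_min_duration(ev, p$min_duration_ms, fs)
}

hilbert_envelope <- function(x) {
  n <- length(x)
  f <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(f * h, inverse = TRUE) / n)
}

detect_hil <- function(xf, fs, p) {
  env <- hilbert_envelope(xf)
  seg_len <- round(p$epoch_s * fs)
  n <- length(env)
  n_seg <- max(1L, floor(n / seg_len))
  mask <- logical(n)
  for (s in seq_len(n_seg)) {
    lo <- (s - 1L) * seg_len + 1L
    hi <- if (s == n_seg) n else s * seg_len
    e <- env[lo:hi]
    thr <- mean(e) + p$threshold_sd * stats::sd(e)
    mask[lo:hi] <- e > thr
  }
  ev <- runs_above(mask)
  ev <- merge_events(ev, p$merge_gap_ms, fs)
  filter_min_duration(ev, p$min_duration_ms, fs)
}

detect_mni <- function(xf, fs, p) {
  w <- max(3L, round(p$energy_window_ms / 1000 * fs))
  energy <- moving_mean(xf^2, w)
  # baseline: 125-ms windows without transient high-frequency content
  bw <- round(p$baseline_window_ms / 1000 * fs)
  n_win <- floor(length(xf) / bw)
  rect <- abs(xf)
  calm_thr <- mean(rect) + p$baseline_sd * stats::sd(rect)
  win_max <- vapply(seq_len(n_win), function(k)
    max(rect[((k - 1) * bw + 1):(k * bw)]), 0)
  baseline_wins <- which(win_max < calm_thr)
  baseline_s <- length(baseline_wins) * bw / fs

  if (baseline_s >= p$min_baseline_s) {
    idx <- unlist(lapply(baseline_wins, function(k)
      ((k - 1) * bw + 1):(k * bw)))
    be <- energy[idx]
    # gamma fit (method of moments) to baseline energy; high-CDF threshold
    m <- mean(be); v <- stats::var(be)
    if (v <= 0) return(data.frame(onset = integer(0), offset = integer(0)))
    shape <- m^2 / v; rate <- m / v
    thr <- stats::qgamma(p$baseline_percentile / 100, shape = shape,
                         rate = rate)
  } else {
    # iterative fallback: empirical percentile, re-estimated after
    # removing suprathreshold samples, until stable
    keep <- rep(TRUE, length(energy))
    thr <- stats::quantile(energy, p$fallback_percentile / 100,
                           names = FALSE)
    for (it in seq_len(5L)) {
      keep_new <- energy <= thr
      thr_new <- stats::quantile(energy[keep_new],
                                 p$fallback_percentile / 100, names = FALSE)
      if (isTRUE(all.equal(thr_new, thr))) break
      thr <- thr_new; keep <- keep_new
    }
  }
  ev <- runs_above(energy > thr)
  ev <- merge_events(ev, p$merge_gap_ms, fs)
  filter_min_duration(ev, p$min_duration_ms, fs)
}

#' Detect HFA events on one channel
#'
#' Band-pass filters the signal (80-500 Hz by default) and applies the
#' requested detector's energy/amplitude criterion. Events are returned
#' sorted, merged, and duration-filtered.
#'
#' @param x Raw (montaged) signal vector.
#' @param detector One of "ste", "sll", "hil", "mni".
#' @param fs Sampling rate (Hz).
#' @param params Parameter list (default: [detector_defaults]); must
#'   include `band`.
#' @param prefiltered Set `TRUE` if `x` is already band-passed.
#' @return `data.frame` with `onset`, `offset` (0-based samples, half-open).
#' @export
detect <- function(x, detector, fs = 1000, params = NULL,
                   prefiltered = FALSE) {
  detector <- tolower(detector)
  stopifnot(detector %in% c("ste", "sll", "hil", "mni"))
  if (is.null(params)) params <- detector_defaults(detector)
  min_len <- switch(detector,
                    mni = round(params$baseline_window_ms / 1000 * fs) * 2L,
                    hil = round(min(params$epoch_s, 1) * fs),
                    round(0.5 * fs))
  if (length(x) < min_len)
    stop("signal shorter than the baseline window of detector ", detector)
  xf <- if (prefiltered) x else
    bandpass(x, band = unlist(params$band), fs = fs,
             order = params$filter_order %||% 128)
  if (all(xf == 0))
    return(data.frame(onset = integer(0), offset = integer(0)))
  fn <- switch(detector, ste = detect_ste, sll = detect_sll,
               hil = detect_hil, mni = detect_mni)
  ev <- fn(xf, fs, params)
  ev[order(ev$onset), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run all four detectors over a montaged recording
#'
#' @param signals Montaged signal matrix (samples x channels, named).
#' @param fs Sampling rate (Hz).
#' @param detectors Character vector of detector ids (default all four).
#' @param params Optional named list of per-detector parameter overrides.
#' @return `data.frame`: `channel`, `detector`, `onset`, `offset`.
#' @export
detect_all <- function(signals, fs = 1000,
                       detectors = c("ste", "sll", "hil", "mni"),
                       params = NULL) {
  defaults <- detector_defaults()
  out <- list()
  for (ch in colnames(signals)) {
    x <- signals[, ch]
    band <- unlist((params[["ste"]] %||% defaults[["ste"]])$band)
    xf <- bandpass(x, band = band, fs = fs)
    for (d in detectors) {
      p <- params[[d]] %||% defaults[[d]]
      ev <- detect(xf, d, fs = fs, params = p, prefiltered = TRUE)
      if (nrow(ev))
        out[[length(out) + 1L]] <- cbind(
          data.frame(channel = ch, detector = d, stringsAsFactors = FALSE),
          ev)
    }
  }
  if (!length(out))
    return(data.frame(channel = character(0), detector = character(0),
                      onset = integer(0), offset = integer(0)))
  do.call(rbind, out)
}
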