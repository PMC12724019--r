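# End-to-end orchestration: simulate -> montage -> detect -> featurize ->
# train/score -> outcome -> report, with per-detector outputs kept
# separate throughout and a JSON run manifest.

#' Detect and featurize one patient's recording
#'
#' Applies the study montage, runs the requested detectors on the montaged
#' signals, computes per-event morphology, aggregates per montage channel,
#' and maps bipolar-pair statistics back to depth contacts (mean of
#' adjacent pairs, single pair at shaft ends).
#'
#' @param signals Samples x channels matrix (raw, named columns).
#' @param electrodes Electrode metadata for this patient.
#' @param fs Sampling rate (Hz).
#' @param epoch_minutes Epoch length (min).
#' @param age Patient age (years).
#' @param detectors Detector ids (default all four).
#' @param tf_cfg Time-frequency config ([tf_config]).
#' @param agg Morphology aggregator ("median"/"mean").
#' @return List: `features` (named list per detector: one row per included
#'   contact with the seven model features), `events` (events with
#'   morphology, on montage channels).
#' @export
featurize_patient <- function(signals, electrodes, fs = 1000,
                              epoch_minutes = 5, age = NA_real_,
                              detectors = c("ste", "sll", "hil", "mni"),
                              tf_cfg = tf_config(), agg = "median") {
  mont <- apply_montage(signals, electrodes)
  events <- detect_all(mont$signals, fs = fs, detectors = detectors)
  morph <- list()
  for (ch in unique(events$channel)) {
    sel <- events$channel == ch
    morph[[length(morph) + 1L]] <-
      event_morphology(mont$signals[, ch], events[sel, , drop = FALSE],
                       fs, tf_cfg)
  }
  events <- if (length(morph)) do.call(rbind, morph) else
    cbind(events, data.frame(duration_ms = numeric(0),
                             max_power_uv2 = numeric(0),
                             peak_freq_hz = numeric(0),
                             entropy = numeric(0)))

  el <- mont$electrodes
  ch_meta <- mont$channels
  num_feats <- c("rate", "median_duration", "median_power", "median_freq",
                 "median_entropy")
  features <- list()
  for (d in detectors) {
    ev_d <- events[events$detector == d, , drop = FALSE]
    # per-montage-channel aggregate rows
    agg_rows <- do.call(rbind, lapply(ch_meta$channel, function(ch)
      aggregate_electrode(ev_d[ev_d$channel == ch, , drop = FALSE],
                          epoch_minutes, region = NA, age = age,
                          agg = agg)))
    rownames(agg_rows) <- ch_meta$channel
    # map to contacts
    rows <- vector("list", nrow(el))
    for (i in seq_len(nrow(el))) {
      nm <- el$name[i]
      if (el$kind[i] == "subdural") {
        vals <- agg_rows[nm, num_feats]
      } else {
        adj <- ch_meta$channel[ch_meta$kind == "pair" &
                                 (ch_meta$contact_a == nm |
                                    ch_meta$contact_b == nm)]
        vals <- as.data.frame(lapply(agg_rows[adj, num_feats, drop = FALSE],
                                     function(v) {
                                       m <- mean(v, na.rm = TRUE)
                                       if (is.nan(m)) NA_real_ else m
                                     }))
      }
      rows[[i]] <- data.frame(vals, region = el$region[i], age = age,
                              patient = el$patient[i], channel = nm,
                              row.names = NULL, stringsAsFactors = FALSE)
    }
    features[[d]] <- do.call(rbind, rows)
  }
  list(features = features, events = events)
}

#' Detect and featurize a whole synthetic cohort
#'
#' Streams patient by patient (signals are synthesized on demand and
#' discarded) and assembles per-detector electrode feature tables with SOZ
#' labels. Spiking-only and resected-other sites are labeled `NA`; filter
#' on `!is.na(label)` for training tables.
#'
#' @param cohort Result of [generate_cohort].
#' @param detectors Detector ids.
#' @param tf_cfg Time-frequency config.
#' @param verbose Print per-patient progress.
#' @return List: `features` (per-detector `data.frame`s with `label`),
#'   `events` (cohort events with morphology).
#' @export
cohort_features <- function(cohort,
                            detectors = c("ste", "sll", "hil", "mni"),
                            tf_cfg = tf_config(), verbose = FALSE) {
  cfg <- cohort$cfg
  feats <- stats::setNames(vector("list", length(detectors)), detectors)
  events <- list()
  for (pid in unique(cohort$patients$patient)) {
    sig <- cohort$recordings[[pid]]
    if (is.null(sig)) sig <- patient_signals(cohort, pid)
    el <- cohort$electrodes[cohort$electrodes$patient == pid, ,
                            drop = FALSE]
    prow <- cohort$patients[cohort$patients$patient == pid, ]
    fp <- featurize_patient(sig, el, fs = cfg$sampling_rate,
                            epoch_minutes = cfg$epoch_minutes,
                            age = prow$age, detectors = detectors,
                            tf_cfg = tf_cfg)
    if (nrow(fp$events)) {
      fp$events$patient <- pid
      events[[length(events) + 1L]] <- fp$events
    }
    for (d in detectors)
      feats[[d]] <- rbind(feats[[d]], fp$features[[d]])
    if (verbose) message(pid, ": ", nrow(fp$events), " events")
  }
  el <- cohort$electrodes
  lab_of <- function(pat, ch) {
    i <- match(paste(pat, ch), paste(el$patient, el$name))
    ifelse(el$soz[i], 1L,
           ifelse(!el$soz[i] & !el$spiking[i] & !el$resected[i], 0L,
                  NA_integer_))
  }
  for (d in detectors)
    feats[[d]]$label <- lab_of(feats[[d]]$patient, feats[[d]]$channel)
  list(features = feats,
       events = if (length(events)) do.call(rbind, events) else NULL)
}

#' Run the whole pipeline from a declarative config
#'
#' Stages: simulate -> write/read cohort files -> montage -> detect ->
#' featurize -> train/score -> outcome -> report. Each stage writes its
#' outputs under `out_dir` (per-detector subdirectories) and appends a
#' manifest entry; rerunning with the same config reproduces identical
#' outputs.
#'
#' @param sim Simulation config ([sim_config]); its seed drives every
#'   stochastic stage.
#' @param out_dir Output directory.
#' @param detectors Detector ids to run.
#' @param cv_k Outer CV folds (reduced automatically for tiny cohorts).
#' @param pseudo_null_models Pseudo-label replicates (0 disables the null
#'   stage).
#' @return Invisible list with the feature tables, model results, outcome
#'   results, and the manifest.
#' @export
run_pipeline <- function(sim = sim_config(n_patients = 2,
                                          channels_per_patient = 20),
                         out_dir = tempfile("hfarun"),
                         detectors = c("ste", "sll", "hil", "mni"),
                         cv_k = 10, pseudo_null_models = 0) {
  detectors <- tolower(detectors)
  bad <- setdiff(detectors, c("ste", "sll", "hil", "mni"))
  if (length(bad)) stop("unknown detector: ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = sim$seed, detectors = detectors,
                   stages = list())
  stamp <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      stage = stage, files = basename(files),
      md5 = unname(tools::md5sum(files)))
  }

  # simulate + serialize
  cohort <- generate_cohort(sim, signals = TRUE)
  cdir <- file.path(out_dir, "cohort")
  write_cohort(cohort, cdir, fs = sim$sampling_rate)
  stamp("simulate", list.files(cdir, full.names = TRUE))

  # round-trip through the on-disk formats, then detect + featurize
  cohort2 <- cohort
  for (pid in names(cohort$recordings)) {
    edf <- read_edf(file.path(cdir, paste0(pid, ".edf")))
    n_samp <- round(sim$epoch_minutes * 60 * sim$sampling_rate)
    cohort2$recordings[[pid]] <- edf$signals[seq_len(n_samp), , drop = FALSE]
  }
  cf <- cohort_features(cohort2, detectors = detectors)
  for (d in detectors) {
    ddir <- file.path(out_dir, d)
    dir.create(ddir, showWarnings = FALSE)
    utils::write.csv(cf$features[[d]],
                     file.path(ddir, "electrode_features.csv"),
                     row.names = FALSE)
  }
  ev_path <- file.path(out_dir, "events.csv")
  utils::write.csv(cf$events, ev_path, row.names = FALSE)
  stamp("detect_featurize", ev_path)

  # train/score per detector (skipped when the cohort is too small)
  models <- list(); scores_by_det <- list()
  for (d in detectors) {
    tbl <- cf$features[[d]]
    tbl <- tbl[!is.na(tbl$label), , drop = FALSE]
    k_eff <- min(cv_k, sum(tbl$label == 1), sum(tbl$label == 0))
    if (k_eff >= 2) {
      cv <- nested_cv_train(tbl, k = k_eff, seed = sim$seed)
      models[[d]] <- cv
      out <- data.frame(patient = tbl$patient, channel = tbl$channel,
                        detector = d, soz_probability = cv$probability)
      scores_by_det[[d]] <- out
      utils::write.csv(out, file.path(out_dir, d, "soz_scores.csv"),
                       row.names = FALSE)
      if (pseudo_null_models > 0) {
        null <- pseudo_label_null(tbl, n_models = pseudo_null_models,
                                  observed_auroc = cv$auroc, k = k_eff,
                                  seed = sim$seed)
        jsonlite::write_json(null[c("null_aurocs", "mean_null_auroc", "p")],
                             file.path(out_dir, d, "pseudo_null.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }

  # outcome stage: biomarker difference from per-electrode scores
  outcome <- list()
  for (d in names(scores_by_det)) {
    sc <- scores_by_det[[d]]
    diffs <- vapply(unique(sc$patient), function(pid) {
      el <- cohort$electrodes[cohort$electrodes$patient == pid &
                                !cohort$electrodes$excluded, ]
      v <- sc$soz_probability[sc$patient == pid]
      names(v) <- sc$channel[sc$patient == pid]
      common <- intersect(names(v), el$name)
      if (!length(common)) return(NA_real_)
      suppressWarnings(
        biomarker_difference(v[common],
                             el$resected[match(common, el$name)]))
    }, 0)
    outcome[[d]] <- data.frame(patient = unique(sc$patient),
                               detector = d, biomarker_difference = diffs)
    utils::write.csv(outcome[[d]],
                     file.path(out_dir, d, "biomarker_difference.csv"),
                     row.names = FALSE)
  }

  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(list(features = cf$features, models = models,
                 outcome = outcome, manifest = manifest,
                 out_dir = out_dir))
}
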