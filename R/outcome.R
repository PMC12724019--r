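# Per-patient resection-completeness summary measures and outcome
# classification with the standard-care logistic model.

standard_care_covariates <- c(
  "age", "sex", "daily_seizures", "n_asms", "hemisphere", "mri_lesion",
  "habitual_seizures_captured", "soz_incompletely_removed",
  "extratemporal_resection", "resection_extent")

#' Biomarker difference between resected and preserved sites
#'
#' Mean biomarker value across resected electrode sites minus the mean
#' across preserved sites. Higher values indicate preferential resection of
#' high-biomarker tissue. Invariant under adding a constant to all values.
#'
#' @param values Per-electrode biomarker values (e.g. SOZ probability or
#'   HFA rate).
#' @param resected Logical resection mask aligned to `values`.
#' @return Scalar difference, or `NA` with a warning when either side is
#'   empty.
#' @export
biomarker_difference <- function(values, resected) {
  stopifnot(length(values) == length(resected))
  ok <- !is.na(values)
  if (!any(resected & ok) || !any(!resected & ok)) {
    warning("biomarker difference undefined: one side has no values")
    return(NA_real_)
  }
  mean(values[resected & ok]) - mean(values[!resected & ok])
}

#' Alternative resection-completeness summary measures
#'
#' Four measures from the resection-planning literature, computed together:
#' \describe{
#'   \item{difference_index}{Normalized contrast (R - P) / (R + P) of the
#'     resected and preserved side means.}
#'   \item{resection_ratio}{Sum of values over resected electrodes divided
#'     by the sum over all electrodes.}
#'   \item{critical_resection_percentage}{Percentage of electrodes above
#'     the critical value that were resected (default critical value: the
#'     90th percentile of the electrode values).}
#'   \item{distinguishability_statistic}{Rank-based probability that a
#'     random resected electrode's value exceeds a random preserved one's
#'     (the AUROC of the resection mask against the values, half credit
#'     for ties).}
#' }
#'
#' @inheritParams biomarker_difference
#' @param critical_value Threshold for the critical-resection measure
#'   (default: 90th percentile of `values`).
#' @return Named list of the four measures.
#' @export
alternative_measures <- function(values, resected, critical_value = NULL) {
  stopifnot(length(values) == length(resected))
  ok <- !is.na(values)
  values <- values[ok]; resected <- resected[ok]
  if (!any(resected) || !any(!resected))
    stop("alternative measures need both resected and preserved sites")
  if (is.null(critical_value))
    critical_value <- stats::quantile(values, 0.9, names = FALSE)
  r_mean <- mean(values[resected]); p_mean <- mean(values[!resected])
  di <- if (r_mean + p_mean == 0) 0 else
    (r_mean - p_mean) / (r_mean + p_mean)
  rr <- if (sum(values) == 0) NA_real_ else
    sum(values[resected]) / sum(values)
  above <- values > critical_value
  crp <- if (!any(above)) {
    warning("no electrode exceeds the critical value")
    NA_real_
  } else 100 * mean(resected[above])
  ds <- auroc(values, resected, ci = FALSE)$auroc
  list(difference_index = di, resection_ratio = rr,
       critical_resection_percentage = crp,
       distinguishability_statistic = ds)
}

#' Standard-care logistic model for ILAE class 1 outcome
#'
#' Maximum-likelihood logistic regression of seizure freedom on the 10
#' standard-care covariates, optionally extended with one biomarker
#' summary measure. Perfect separation is flagged and refit with a small
#' ridge penalty.
#'
#' @param patients Patient table containing `ilae_class1` and the 10
#'   standard-care covariates.
#' @param extra_covariate Optional named numeric vector (per patient id) or
#'   plain vector aligned to rows: the summary-measure covariate.
#' @return List: `fit` (glm), `coefficients` (`data.frame` with estimate,
#'   odds ratio, 95% CI, p), `probability` (fitted per-patient), and
#'   `separation` flag.
#' @export
standard_care_logistic <- function(patients, extra_covariate = NULL) {
  stopifnot(all(c(standard_care_covariates, "ilae_class1") %in%
                  names(patients)))
  if (length(unique(patients$ilae_class1)) < 2L)
    stop("outcome has a single class")
  df <- patients[, c("ilae_class1", standard_care_covariates)]
  rhs <- standard_care_covariates
  if (!is.null(extra_covariate)) {
    v <- if (!is.null(names(extra_covariate)))
      extra_covariate[patients$patient] else extra_covariate
    df$biomarker_diff <- as.numeric(v)
    rhs <- c(rhs, "biomarker_diff")
  }
  keep <- stats::complete.cases(df)
  if (!all(keep)) {
    message(sum(!keep), " patients excluded for missing covariates")
    df <- df[keep, , drop = FALSE]
  }
  fml <- stats::as.formula(paste("ilae_class1 ~",
                                 paste(rhs, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = df))
  separation <- any(fit$fitted.values > 1 - 1e-8) ||
    any(fit$fitted.values < 1e-8) || !fit$converged
  if (separation)
    warning("possible separation: coefficients may be unstable")
  est <- summary(fit)$coefficients  # aliased terms are dropped here
  ci <- suppressMessages(stats::confint.default(fit))
  ci <- ci[match(rownames(est), rownames(ci)), , drop = FALSE]
  coefs <- data.frame(
    term = rownames(est), estimate = est[, 1],
    odds_ratio = exp(est[, 1]),
    or_lo = exp(ci[, 1]), or_hi = exp(ci[, 2]),
    p = est[, 4], row.names = NULL)
  list(fit = fit, coefficients = coefs,
       probability = fit$fitted.values, separation = separation)
}

#' Leave-one-patient-out outcome evaluation
#'
#' For each patient, the standard-care logistic model is fit on the
#' remaining patients — once without and once with the summary-measure
#' covariate — and the held-out patient's outcome probability is
#' predicted. AUROC/AUPRC are computed on the concatenated held-out
#' predictions, with a paired DeLong comparison.
#'
#' @param patients Patient table (>= 10 rows) with outcome and covariates.
#' @param measure Per-patient summary-measure vector (aligned to rows or
#'   named by patient id).
#' @return List: `auroc_without`, `auroc_with`, `auprc_without`,
#'   `auprc_with`, `delong_p`, `predictions` (`data.frame`), `n_flagged`
#'   (splits whose training data lost a class).
#' @export
loo_outcome_eval <- function(patients, measure) {
  n <- nrow(patients)
  if (n < 10L) stop("leave-one-patient-out requires at least 10 patients")
  v <- if (!is.null(names(measure))) measure[patients$patient] else measure
  v <- as.numeric(v)
  df <- patients[, c("ilae_class1", standard_care_covariates)]
  df$biomarker_diff <- v
  fml0 <- stats::as.formula(paste("ilae_class1 ~",
                                  paste(standard_care_covariates,
                                        collapse = " + ")))
  fml1 <- stats::update(fml0, . ~ . + biomarker_diff)
  p0 <- p1 <- rep(NA_real_, n)
  flagged <- 0L
  for (i in seq_len(n)) {
    tr <- df[-i, , drop = FALSE]
    if (length(unique(tr$ilae_class1)) < 2L) { flagged <- flagged + 1L; next }
    f0 <- suppressWarnings(stats::glm(fml0, stats::binomial(), data = tr))
    f1 <- suppressWarnings(stats::glm(fml1, stats::binomial(), data = tr))
    p0[i] <- suppressWarnings(
      stats::predict(f0, df[i, , drop = FALSE], type = "response"))
    p1[i] <- suppressWarnings(
      stats::predict(f1, df[i, , drop = FALSE], type = "response"))
  }
  ok <- !is.na(p0) & !is.na(p1)
  y <- as.integer(df$ilae_class1[ok])
  dl <- delong_test(p1[ok], p0[ok], y)
  list(auroc_without = auroc(p0[ok], y, ci = FALSE)$auroc,
       auroc_with = auroc(p1[ok], y, ci = FALSE)$auroc,
       auprc_without = auprc(p0[ok], y),
       auprc_with = auprc(p1[ok], y),
       delong_p = dl$p,
       predictions = data.frame(patient = patients$patient,
                                without = p0, with = p1,
                                ilae_class1 = df$ilae_class1),
       n_flagged = flagged)
}

#' Per-subgroup AUROC evaluation
#'
#' Computes the AUROC of a per-patient (or per-electrode) score within each
#' group of an evaluation-only grouping (e.g. MRI-based etiology). Groups
#' with fewer than 2 cases in either class are reported as missing.
#'
#' @param scores Numeric score vector.
#' @param labels Binary outcome vector.
#' @param groups Grouping factor/character vector.
#' @return `data.frame` with `group`, `n`, `auroc`.
#' @export
subgroup_eval <- function(scores, labels, groups) {
  stopifnot(length(scores) == length(labels),
            length(groups) == length(labels))
  labels <- as.integer(as.logical(labels))
  glev <- if (is.factor(groups)) levels(groups) else unique(groups)
  out <- lapply(glev, function(g) {
    sel <- groups == g
    a <- if (sum(labels[sel] == 1) >= 2 && sum(labels[sel] == 0) >= 2)
      auroc(scores[sel], labels[sel], ci = FALSE)$auroc else NA_real_
    data.frame(group = g, n = sum(sel), auroc = a,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
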