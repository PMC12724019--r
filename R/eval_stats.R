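#' Area under the ROC curve with a DeLong confidence interval
#'
#' Computes the AUROC as the Mann-Whitney probability that a randomly chosen
#' positive outranks a randomly chosen negative, with half credit for ties.
#' The 95% confidence interval uses the DeLong asymptotic variance of the
#' same construction (via \pkg{pROC}).
#'
#' @param scores Numeric vector of classifier scores (higher = more positive).
#' @param labels Binary vector (0/1 or logical) of true class membership.
#' @param ci Logical; compute the DeLong 95% CI (default `TRUE`).
#' @return A list with `auroc`, and (if `ci`) `ci95` as a length-2 vector.
#' @export
auroc <- function(scores, labels, ci = TRUE) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("auroc requires both classes present")
  r <- rank(scores, ties.method = "average")
  value <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  out <- list(auroc = value)
  if (ci) {
    ci95 <- tryCatch(
      as.numeric(pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<"),
                              method = "delong"))[c(1, 3)],
      error = function(e) c(NA_real_, NA_real_))
    out$ci95 <- ci95
  }
  out
}

#' Area under the precision-recall curve
#'
#' Interpolation-free step summation (average precision): the sum over
#' recall increments of the precision attained at each score threshold,
#' with tied scores treated as a single threshold block. For a random
#' scorer the expectation approaches the positive prevalence.
#'
#' @inheritParams auroc
#' @return Scalar AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("auprc requires at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # collapse tied scores into threshold blocks
  block <- cumsum(!duplicated(s))
  tp_block <- tapply(y, block, sum)
  n_block <- tapply(y, block, length)
  tp <- cumsum(tp_block)
  n_at <- cumsum(n_block)
  precision <- tp / n_at
  recall <- tp / n_pos
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

#' Paired DeLong test for the difference of two AUROCs
#'
#' Two-sided p-value for the AUROC difference of two score vectors computed
#' on the same cases (paired design), using the DeLong covariance.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared binary labels.
#' @return List with `p`, `auroc_a`, `auroc_b`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (length(unique(labels)) < 2L) stop("delong_test requires both classes")
  a <- auroc(scores_a, labels, ci = FALSE)$auroc
  b <- auroc(scores_b, labels, ci = FALSE)$auroc
  if (isTRUE(all.equal(scores_a, scores_b))) {
    return(list(p = 1, auroc_a = a, auroc_b = b))
  }
  ra <- pROC::roc(labels, scores_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, scores_b, quiet = TRUE, direction = "<")
  p <- tryCatch(
    pROC::roc.test(ra, rb, method = "delong", paired = TRUE)$p.value,
    error = function(e) NA_real_)
  if (is.na(p) || is.nan(p)) p <- 1  # zero-variance difference
  list(p = p, auroc_a = a, auroc_b = b)
}

#' Bootstrap paired test for a metric difference
#'
#' Resamples cases with replacement, recomputes `metric_fn` for both score
#' vectors per replicate, and reports a two-sided p-value for the observed
#' difference from the replicate distribution. Replicates that lose a class
#' are redrawn (with a cap).
#'
#' @param metric_fn Function `(scores, labels) -> scalar` (e.g. [auprc]).
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Shared binary labels.
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return List with `p`, `observed_diff`, `boot_diffs`.
#' @export
bootstrap_paired_test <- function(metric_fn, scores_a, scores_b, labels,
                                  n_boot = 2000, seed) {
  labels <- as.integer(as.logical(labels))
  n <- length(labels)
  stopifnot(length(scores_a) == n, length(scores_b) == n, !missing(seed))
  if (isTRUE(all.equal(scores_a, scores_b))) {
    return(list(p = 1, observed_diff = 0, boot_diffs = numeric(0)))
  }
  obs <- metric_fn(scores_a, labels) - metric_fn(scores_b, labels)
  set.seed(as.integer(seed))
  diffs <- numeric(n_boot)
  max_redraw <- 50L
  for (i in seq_len(n_boot)) {
    for (attempt in seq_len(max_redraw)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    if (length(unique(labels[idx])) < 2L) {
      warning("bootstrap replicate with a single class after redraw cap")
      diffs[i] <- NA_real_
      next
    }
    diffs[i] <- metric_fn(scores_a[idx], labels[idx]) -
      metric_fn(scores_b[idx], labels[idx])
  }
  diffs <- diffs[!is.na(diffs)]
  # two-sided: how extreme is 0 within the replicate distribution of diffs
  p_lo <- mean(diffs <= 0)
  p_hi <- mean(diffs >= 0)
  p <- min(1, 2 * min(p_lo, p_hi))
  if (p == 0) p <- 1 / (length(diffs) + 1)
  list(p = p, observed_diff = obs, boot_diffs = diffs)
}

#' Wilcoxon signed-rank test with effect size r = Z / sqrt(N)
#'
#' Paired signed-rank test on per-patient value pairs. Zero differences are
#' dropped; the normal approximation with tie correction gives Z, and the
#' effect size is r = Z / sqrt(N) carrying the sign of the median
#' difference. Interpretation thresholds: small r ~ 0.1, medium r ~ 0.3,
#' large r >= 0.5.
#'
#' @param a,b Paired numeric vectors (e.g. per-patient medians at SOZ and
#'   non-epileptic sites).
#' @return List with `p`, `r`, `z`, `n` (pairs entering the test).
#' @export
wilcoxon_effect <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d)]
  if (all(d == 0)) return(list(p = 1, r = 0, z = 0, n = length(d)))
  med_sign <- sign(stats::median(d[d != 0]))
  d <- d[d != 0]
  n <- length(d)
  if (n < 6L) stop("wilcoxon_effect requires at least 6 non-tied pairs")
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  tie_tab <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (w_pos - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  r <- abs(z) / sqrt(n) * med_sign
  list(p = p, r = r, z = z, n = n)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; p-value from the
#' t approximation.
#'
#' @param x,y Numeric vectors of equal length (N >= 4).
#' @return List with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Bonferroni significance gate for the four-detector comparisons
#'
#' The family of comparisons is run once per HFA detector (STE, SLL, HIL,
#' MNI); the two-sided threshold is alpha / 4 with strict inequality.
#'
#' @param p_values Numeric vector of p-values (one per detector comparison).
#' @param alpha Family-wise level (default 0.05, giving the 0.0125 gate).
#' @return Logical vector: `TRUE` where p < alpha / 4.
#' @export
bonferroni_gate <- function(p_values, alpha = 0.05) {
  p_values < alpha / 4
}
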