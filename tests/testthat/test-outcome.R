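test_that("biomarker difference contrasts resected against preserved means", {
  expect_equal(biomarker_difference(c(0.8, 0.6, 0.2, 0.4),
                                    c(TRUE, TRUE, FALSE, FALSE)), 0.4)
  expect_equal(biomarker_difference(c(1, 1, 0, 0),
                                    c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(biomarker_difference(c(0.3, 0.3, 0.3, 0.3),
                                    c(TRUE, FALSE, TRUE, FALSE)), 0)
  expect_warning(d <- biomarker_difference(1:4, rep(TRUE, 4)), "undefined")
  expect_true(is.na(d))
  # shift invariance
  v <- c(0.9, 0.1, 0.5, 0.2); m <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(biomarker_difference(v + 5, m), biomarker_difference(v, m))
})

test_that("alternative summary measures honor their closed forms", {
  v <- rep(2, 10); m <- rep(c(TRUE, FALSE), 5)
  am <- alternative_measures(v, m, critical_value = 1)
  expect_equal(am$resection_ratio, 0.5)
  expect_equal(am$difference_index, 0)
  expect_equal(am$distinguishability_statistic, 0.5)

  v2 <- c(4, 3, 2, 1); m2 <- c(TRUE, TRUE, FALSE, FALSE)
  am2 <- alternative_measures(v2, m2, critical_value = 2.5)
  expect_equal(am2$resection_ratio, 0.7)
  expect_equal(am2$distinguishability_statistic, 1)
  expect_equal(am2$critical_resection_percentage, 100)
  expect_warning(
    am3 <- alternative_measures(v2, m2, critical_value = 10),
    "critical value")
  expect_true(is.na(am3$critical_resection_percentage))
  # scale invariance of the resection ratio
  expect_equal(alternative_measures(7 * v2, m2)$resection_ratio,
               alternative_measures(v2, m2)$resection_ratio)
})

test_that("the distinguishability statistic equals exhaustive pair counting", {
  set.seed(14)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    v <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    m <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    am <- alternative_measures(v, m, critical_value = -1)
    expect_equal(am$distinguishability_statistic,
                 auroc_oracle(v, as.integer(m)))
  }
})

test_that("the standard-care logistic model recovers a 2x2 odds ratio", {
  # one informative binary covariate in an otherwise symmetric design:
  # cell counts (20, 10, 10, 20) give a cross-product odds ratio of 4
  cells <- expand.grid(x = c(0, 1), y = c(0, 1))
  counts <- c(20, 10, 10, 20)
  rows <- do.call(rbind, lapply(1:4, function(i)
    cells[rep(i, counts[i]), ]))
  n <- nrow(rows)
  pats <- data.frame(
    patient = sprintf("P%03d", 1:n),
    age = 10, sex = rep(c("F", "M"), n / 2),
    daily_seizures = rows$x == 1, n_asms = 2,
    hemisphere = rep(c("L", "R"), n / 2), mri_lesion = TRUE,
    habitual_seizures_captured = TRUE, soz_incompletely_removed = FALSE,
    extratemporal_resection = TRUE, resection_extent = 0.1,
    ilae_class1 = rows$y == 1)
  fit <- standard_care_logistic(pats)
  or <- fit$coefficients$odds_ratio[
    fit$coefficients$term == "daily_seizuresTRUE"]
  expect_equal(or, 4, tolerance = 1e-6)
  expect_error(
    standard_care_logistic(transform(pats, ilae_class1 = TRUE)),
    "single class")
})

test_that("the outcome link coefficient is recovered with a confident odds ratio", {
  co <- generate_cohort(sim_config(n_patients = 400, seed = 7),
                        signals = FALSE)
  d <- true_rate_differences(co)
  keep <- !is.na(d)
  fit <- standard_care_logistic(co$patients[keep, ], d[keep])
  cf <- fit$coefficients[fit$coefficients$term == "biomarker_diff", ]
  expect_gt(cf$odds_ratio, 1)
  expect_gt(cf$or_lo, 1)
  expect_lt(cf$p, 0.05)
})

test_that("leave-one-patient-out evaluation enforces its preconditions and null behavior", {
  # LOO under an independent outcome is slightly pessimistic per split,
  # so the null band is checked on the mean over seeds
  aucs <- vapply(c(15, 16, 17), function(s) {
    co <- generate_cohort(sim_config(n_patients = 120, outcome_link = 0,
                                     seed = s), signals = FALSE)
    d <- true_rate_differences(co)
    keep <- !is.na(d)
    loo_outcome_eval(co$patients[keep, ], d[keep])$auroc_with
  }, 0)
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
  co <- generate_cohort(sim_config(n_patients = 12, seed = 15),
                        signals = FALSE)
  expect_error(loo_outcome_eval(co$patients[1:5, ], rep(1, 5)),
               "10 patients")
})

test_that("subgroup evaluation reduces to the ungrouped metric and tolerates small groups", {
  set.seed(16)
  s <- stats::runif(40); y <- stats::rbinom(40, 1, 0.5)
  one <- subgroup_eval(s, y, rep("all", 40))
  expect_equal(one$auroc, auroc(s, y, ci = FALSE)$auroc)
  g <- c(rep("big", 38), "tiny", "tiny")
  res <- subgroup_eval(s, y, g)
  expect_true(is.na(res$auroc[res$group == "tiny"]))
  # empty factor level: reported missing, run continues
  gf <- factor(g, levels = c("big", "tiny", "absent"))
  resf <- subgroup_eval(s, y, gf)
  expect_true(is.na(resf$auroc[resf$group == "absent"]))
  expect_equal(resf$n[resf$group == "absent"], 0)
})
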