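#!/usr/bin/env Rscript
# Evaluate resection-completeness summary measures against the ILAE class 1
# outcome: univariate and standard-care-adjusted logistic models,
# leave-one-patient-out discrimination, the four alternative summary
# measures, and an etiology-style subgroup inversion.

library(hfatools)

co <- generate_cohort(sim_config(n_patients = 400, seed = 1005),
                      signals = FALSE)
d <- vapply(co$patients$patient, function(pid) {
  el <- co$electrodes[co$electrodes$patient == pid &
                        !co$electrodes$excluded, ]
  suppressWarnings(biomarker_difference(el$true_rate, el$resected))
}, 0)
keep <- !is.na(d)
cat("Patients with a defined biomarker difference:", sum(keep), "of",
    length(d), "\n")

fit <- standard_care_logistic(co$patients[keep, ], d[keep])
cf <- fit$coefficients[fit$coefficients$term == "biomarker_diff", ]
cat(sprintf("Biomarker-difference OR: %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
            cf$odds_ratio, cf$or_lo, cf$or_hi, cf$p))

loo <- loo_outcome_eval(co$patients[keep, ], d[keep])
cat(sprintf("LOO AUROC without biomarker: %.3f   with: %.3f (DeLong p = %.3g)\n",
            loo$auroc_without, loo$auroc_with, loo$delong_p))

pid1 <- co$patients$patient[keep][1]
el1 <- co$electrodes[co$electrodes$patient == pid1 &
                       !co$electrodes$excluded, ]
am <- alternative_measures(el1$true_rate, el1$resected)
cat(sprintf(paste0("Alternative measures (%s): difference index %.2f, ",
                   "resection ratio %.2f,\n  critical resection %.0f%%, ",
                   "distinguishability %.2f\n"),
            pid1, am$difference_index, am$resection_ratio,
            am$critical_resection_percentage,
            am$distinguishability_statistic))

# inverted-link subgroup: resecting high-biomarker tissue predicts worse
# outcome, as in destructive etiologies
neg <- generate_cohort(sim_config(n_patients = 150, outcome_link = -1.5,
                                  seed = 1006), signals = FALSE)
dn <- vapply(neg$patients$patient, function(pid) {
  el <- neg$electrodes[neg$electrodes$patient == pid &
                         !neg$electrodes$excluded, ]
  suppressWarnings(biomarker_difference(el$true_rate, el$resected))
}, 0)
kn <- !is.na(dn)
sg <- subgroup_eval(c(d[keep], dn[kn]),
                    c(co$patients$ilae_class1[keep],
                      neg$patients$ilae_class1[kn]),
                    rep(c("positive_link", "inverted_link"),
                        c(sum(keep), sum(kn))))
print(sg)

dir.create("results", showWarnings = FALSE)
utils::write.csv(
  data.frame(loo$predictions, biomarker_difference = d[keep]),
  "results/outcome_predictions.csv", row.names = FALSE)
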