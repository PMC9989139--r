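#!/usr/bin/env Rscript
# Simulate a synthetic instructed-threat cohort at desk scale and check the
# planted behavioural effects: higher threat ratings and heart rate under
# CS+ than CS-, and a rating-heart-rate correlation near the planted 0.5.
#
# Writes: results/cohort/ (series, behaviour, ground truth, metadata),
#         results/behaviour_tests.csv

suppressPackageStartupMessages(library(threatnets))

out_root <- "results"
dir.create(out_root, showWarnings = FALSE)

cfg <- synthetic_config(
  n_subjects = 6,
  n_rois = 20,
  n_trials_per_condition = c("CS+" = 12, "CS-" = 8),
  coupling_spec = data.frame(source = c(1, 3), target = c(2, 4),
                             band = "theta", coef = c(0.4, 0.4)),
  switch_rates = c("CS+" = 0.4, "CS-" = 0.2),
  seed = 20260927L
)
res <- generate_cohort(cfg, file.path(out_root, "cohort"), overwrite = TRUE)

beh <- res$behaviour
rows <- lapply(c("rating", "heart_rate"), function(var) {
  a <- beh[[var]][beh$condition == "CS+"]
  b <- beh[[var]][beh$condition == "CS-"]
  tt <- paired_ttest(a, b, alpha = 0.01)
  data.frame(variable = var, mean_csplus = mean(a), mean_csminus = mean(b),
             t = tt$t, p = tt$p, significant = tt$significant)
})
bt <- do.call(rbind, rows)
write.csv(bt, file.path(out_root, "behaviour_tests.csv"), row.names = FALSE)

# rating-heart coupling within condition (pooling conditions would conflate
# the planted CS+ shift with the shared latent factor)
sel <- beh$condition == "CS+"
rh <- correlate_bonferroni(beh$rating[sel], beh$heart_rate[sel])

cat("Cohort written to", file.path(out_root, "cohort"), "\n")
print(bt, digits = 3)
cat(sprintf("rating-heart correlation within CS+: r = %.2f (planted ~0.5, n = %d)\n",
            rh$r, sum(sel)))
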