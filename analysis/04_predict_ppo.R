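#!/usr/bin/env Rscript
# Stage 4: predicted postoperative lung function for the stage-3 cohort,
# by anatomical segment counting (pre x [1 - S x 0.0526]) and by the
# well-aerated-lung ratio (pre x [1 - WAL_lobe / WAL_total]).

suppressPackageStartupMessages(library(walqct))

coh <- read_cohort_csv("results/cohort.csv")
pred <- predict_cohort(coh)
write.csv(pred, "results/predictions.csv", row.names = FALSE)

cat("Predictions written to results/predictions.csv\n\n")
cat(sprintf("Median ASC ppo-FEV1: %.2f L | median WAL ppo-FEV1: %.2f L\n",
            median(pred$asc_ppo_fev1_l), median(pred$wal_ppo_fev1_l)))
cat(sprintf("Median ASC ppo-%%DLCO: %.0f%% | median WAL ppo-%%DLCO: %.0f%%\n",
            median(pred$asc_ppo_dlco_pct), median(pred$wal_ppo_dlco_pct)))
cat(sprintf("Segmentectomy rows with proportionally scaled lobe WAL: %d\n",
            sum(pred$wal_scaled)))

# among patients whose resected-lobe WAL share exceeds S x 0.0526 the WAL
# prediction is necessarily the more conservative of the two
share <- pred$wal_lobe_used_l / pred$wal_total_l
high <- share > coh$segments_resected * 0.0526
cat(sprintf("\nPatients with WAL share above S x 0.0526: %d/%d;\n",
            sum(high), nrow(coh)))
cat(sprintf("  among them WAL ppo < ASC ppo in %d/%d (expected: all)\n",
            sum(pred$wal_ppo_fev1_l[high] < pred$asc_ppo_fev1_l[high]),
            sum(high)))
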