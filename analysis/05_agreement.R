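#!/usr/bin/env Rscript
# Stage 5: agreement analysis between the two predictors and the measured
# postoperative values: Spearman rho, Bland-Altman limits of agreement,
# absolute-agreement ICC with banded interpretation, Wilcoxon signed-rank.
# Writes the six-comparison report and Bland-Altman plots.

suppressPackageStartupMessages(library(walqct))

coh <- read_cohort_csv("results/cohort.csv")
pred <- predict_cohort(coh)
rep <- build_report(coh, pred)

write_report_csv(rep, "results/report.csv")
write_report_json(rep, "results/report.json")
print(rep)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("results/figures", showWarnings = FALSE)
  plots <- list(
    list(a = pred$wal_ppo_fev1_l, b = coh$post_fev1_l,
         lab = "WAL ppo-FEV1 vs measured postoperative FEV1 (L)",
         file = "ba_wal_fev1.png"),
    list(a = pred$wal_ppo_dlco_pct, b = coh$post_dlco_pct,
         lab = "WAL ppo-%DLCO vs measured postoperative %DLCO",
         file = "ba_wal_dlco.png"))
  for (p in plots) {
    ba <- bland_altman(p$a, p$b)
    g <- ggplot(data.frame(m = ba$means, d = ba$differences), aes(m, d)) +
      geom_point(alpha = 0.7) +
      geom_hline(yintercept = ba$bias, linetype = "solid") +
      geom_hline(yintercept = c(ba$loa_low, ba$loa_high), linetype = "dashed") +
      labs(x = "Mean of methods", y = "Difference (predicted - measured)",
           title = p$lab,
           subtitle = sprintf("bias %.2f, LoA [%.2f, %.2f]",
                              ba$bias, ba$loa_low, ba$loa_high)) +
      theme_minimal()
    ggsave(file.path("results/figures", p$file), g, width = 5, height = 4,
           dpi = 120)
  }
  cat("\nBland-Altman plots in results/figures/\n")
}
cat("Report written to results/report.{csv,json}\n")
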