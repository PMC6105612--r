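#!/usr/bin/env Rscript
# Multi-rater agreement on the packaged visual fluorescence grades: per-item
# modal agreement, overall pairwise agreement, fixed- and free-marginal
# kappa, and the intrarater repeat-scoring summary.

suppressPackageStartupMessages(library(ppixquant))
dir.create("results", showWarnings = FALSE)

scores <- ppix_grading_scores()
s <- agreement_summary(scores)

cat("Per-standard modal agreement (%):\n")
print(s$per_item_modal_pct)
cat(sprintf("\nOverall pairwise interobserver agreement: %.1f%%\n",
            s$overall_pairwise_pct))
cat(sprintf("Fixed-marginal (Fleiss) kappa:            %.1f%%\n",
            s$fleiss_kappa_pct))
cat(sprintf("Free-marginal kappa (k = 5):              %.1f%%\n",
            s$free_marginal_kappa_pct))

intra <- intrarater_agreement(synthetic_first_attempt(), as.matrix(scores))
cat(sprintf("\nIntrarater agreement: mean %.0f%% (sd %.0f%%) across %d observers\n",
            intra$mean, intra$sd, length(intra$per_rater)))

jsonlite::write_json(
  list(per_item_modal_pct = unname(s$per_item_modal_pct),
       overall_pairwise_pct = s$overall_pairwise_pct,
       fleiss_kappa_pct = s$fleiss_kappa_pct,
       free_marginal_kappa_pct = s$free_marginal_kappa_pct,
       intrarater_mean_pct = intra$mean, intrarater_sd_pct = intra$sd),
  "results/agreement.json", auto_unbox = TRUE, digits = NA)
cat("Wrote results/agreement.json\n")
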