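#!/usr/bin/env Rscript
# Photobleaching kinetics on the normalized series: per-ROI logarithmic
# decay fits, two-point half-lives, and percent decay with a paired t-test
# between the first and 10-minute frames.

suppressPackageStartupMessages(library(ppixquant))
if (!file.exists("results/normalized_timeseries.csv"))
  stop("run analysis/03_quantify_normalize.R first")

ns <- read.csv("results/normalized_timeseries.csv", comment.char = "#")

# Average the normalized series over specimens per ROI, then fit.
agg <- aggregate(normalized_pct ~ roi + time_min, ns, mean)
fits <- fit_log_decay_table(agg, value = "normalized_pct", time_offset = 1)
print(transform(fits, c = round(c, 3), y0 = round(y0, 2), r2 = round(r2, 3)))
write.csv(fits, "results/kinetics_fits.csv", row.names = FALSE)

tumor <- agg[agg$roi == "tumor", ]
tumor <- tumor[order(tumor$time_min), ]
hl <- half_life_two_point(0, tumor$normalized_pct[tumor$time_min == 0],
                          30, tumor$normalized_pct[tumor$time_min == 30])
cat(sprintf("\nTumor two-point half-life (0 vs 30 min): %.1f min\n", hl))
cat(sprintf("Tumor percent change 0 -> 10 min: %.1f%%\n",
            percent_change(tumor, 0, 10, value = "normalized_pct")))

# Paired comparison of per-specimen tumor values at 0 vs 10 min
t0 <- ns$normalized_pct[ns$roi == "tumor" & ns$time_min == 0]
t10 <- ns$normalized_pct[ns$roi == "tumor" & ns$time_min == 10]
ht <- compare_groups(t0, t10, paired = TRUE)
cat(sprintf("Paired t-test t(%d) = %.2f, p = %.3g\n",
            ht$df, ht$statistic, ht$p_value))
cat("Wrote results/kinetics_fits.csv\n")
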