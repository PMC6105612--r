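#!/usr/bin/env Rscript
# Internal CCD vs external filtered camera: render the identical scenes
# through both camera models and compare the tumor-to-background ratio
# trajectories. Blue-to-red spillover in the internal camera compresses the
# ratio toward 1.

suppressPackageStartupMessages(library(ppixquant))
dir.create("results", showWarnings = FALSE)

design <- study_design(n_specimens = 6, shape = c(256, 256), pitch_mm = 0.2,
                       roi_radius_px = 25,
                       cameras = list(external = external_camera(),
                                      internal = internal_camera()),
                       seed = 404)
ts <- run_study(design)$timeseries

tbr <- do.call(rbind, lapply(split(ts, ts[c("specimen", "camera")], drop = TRUE),
  function(sub) cbind(specimen = sub$specimen[1], camera = sub$camera[1],
                      tumor_background_ratio(sub))))
agg <- aggregate(ratio ~ camera + time_min, tbr, mean)
wide <- reshape(agg, idvar = "time_min", timevar = "camera", direction = "wide")
names(wide) <- sub("ratio\\.", "tbr_", names(wide))
print(transform(wide, tbr_external = round(tbr_external, 2),
                tbr_internal = round(tbr_internal, 2)))

cat(sprintf("\nMean TBR at t = 0: external %.2f vs internal %.2f\n",
            wide$tbr_external[wide$time_min == 0],
            wide$tbr_internal[wide$time_min == 0]))
cat("The internal camera's spillover floor compresses the ratio at every frame.\n")
write.csv(wide, "results/camera_comparison.csv", row.names = FALSE)
cat("Wrote results/camera_comparison.csv\n")
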