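#!/usr/bin/env Rscript
# Fluorescence line-scan analysis: simulate noisy line profiles with a
# Gaussian peak at the cell edge, register them to the reference-channel
# maximum, average as percent-of-max, and compute an edge-enrichment ratio
# on a synthetic two-band image.

suppressMessages(library(cellmig))
dir.create("results", showWarnings = FALSE)

# 15 line scans (as commonly acquired per condition), peak planted at
# varying positions to exercise registration
positions <- seq(4, 8, length.out = 15)
profs <- lapply(seq_along(positions), function(i) {
  gen_profiles(profile_sim_config(length_um = 12, step_um = 0.1,
                                  peak_pos_um = positions[i],
                                  peak_sigma_um = 0.6, peak_amp = 100,
                                  background = 10, noise_sd = 3,
                                  seed = 300 + i), 1)$profiles[[1]]
})
reg <- register_profiles(profs, mode = "edge", window_um = c(-2.5, 2.5))
cat(sprintf("registered %d of %d scans (%d rejected)\n",
            length(reg$registered), length(profs), reg$rejected))
avg <- average_profiles(reg$registered, normalize = "percent_max")
write.csv(avg, "results/line_scan_average.csv", row.names = FALSE)
at0 <- avg[abs(avg$distance_um) < 1e-9, ]
cat(sprintf("mean intensity at the registered edge: %.1f%% +/- %.2f (SEM, n = %d)\n",
            at0$mean, at0$sem, at0$n))

# edge enrichment: a band at the lamellipodial edge twice as bright as a
# same-sized band beneath it
img <- matrix(50, 40, 40)
img[1:5, ] <- 100
edge_roi <- matrix(FALSE, 40, 40); edge_roi[1:5, ] <- TRUE
inner_roi <- matrix(FALSE, 40, 40); inner_roi[8:12, ] <- TRUE
fold <- edge_enrichment(img, edge_roi, inner_roi)
cat(sprintf("edge enrichment fold ratio: %.2f (planted 2.0)\n", fold))
write.csv(data.frame(fold_ratio = fold), "results/edge_enrichment.csv",
          row.names = FALSE)
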