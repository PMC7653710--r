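#!/usr/bin/env Rscript

# Skeletonize microglia on dedicated plaque-free fields and measure
# per-cell morphology: process endpoints, junctions and total process
# length, compared against the generator's planted process topology.

library(plaqband)

dir.create("results", showWarnings = FALSE)

rows <- list()
for (k in 1:6) {
  cfg <- section_config(field_size_um = c(300, 300), plaque_density = 0,
                        background_microglia_density = 60,
                        noise_sigma = 0, background_gradient_amp = 0,
                        microglia_min_gap_um = 42, seed = 1000 + k)
  s <- generate_section(cfg)
  seg <- segment_channel(s$stack, "microglia", method = "li", sigma_px = 1)
  cells <- select_cells(skeletonize(seg$mask), soma_mask(seg$mask, 1),
                        pixel_size_um = 1, min_length_um = 5,
                        max_length_um = 1000, prune_um = 3)
  for (cell in cells$cells) {
    idx <- which(cell$mask)
    cy <- mean((idx - 1) %% 300); cx <- mean((idx - 1) %/% 300)
    g <- s$gt$microglia[[which.min(vapply(s$gt$microglia, function(g)
      (g$y_um - cy)^2 + (g$x_um - cx)^2, 1))]]
    rows[[length(rows) + 1L]] <- data.frame(
      field = k, cell_id = cell$cell_id,
      endpoints = cell$n_endpoints, endpoints_gt = g$endpoint_count,
      branch_points = cell$n_branch_points,
      length_um = cell$total_length_um,
      length_gt_um = g$total_process_length_um)
  }
}
cells <- do.call(rbind, rows)
write.csv(cells, "results/morphometry_cells.csv", row.names = FALSE)

cat("Measured", nrow(cells), "cells\n")
cat(sprintf("Endpoint counts exact for %d/%d cells\n",
            sum(cells$endpoints == cells$endpoints_gt), nrow(cells)))
cat(sprintf("Median |length error|: %.1f%%\n",
            100 * median(abs(cells$length_um - cells$length_gt_um) /
                         cells$length_gt_um)))
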