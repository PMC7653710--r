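#!/usr/bin/env Rscript

# Simulate a small two-group imaging experiment: control mice versus a
# Western-diet-like condition in which plaque-associated microglial
# clustering is suppressed (condition factor 0.6). Three sections per
# animal, three animals per group here, written as TIFFs with ground truth
# so the later stages can be rerun from disk.

library(plaqband)

out <- "results/sections"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ctrl <- section_config(field_size_um = c(400, 400), plaque_density = 40,
                       microglia_per_plaque_mean = 8, condition_factor = 1,
                       seed = 1)
cond <- ctrl
cond$condition_factor <- 0.6

cohort <- generate_cohort(ctrl, cond, n_per_group = 9, seed = 20260131)

manifest <- data.frame(section = seq_along(cohort),
                       group = vapply(cohort, `[[`, "", "group"),
                       animal = rep(rep(1:3, each = 3), 2))
for (i in seq_along(cohort)) {
  tag <- sprintf("section_%02d", i)
  write_section_tiff(cohort[[i]]$stack, file.path(out, paste0(tag, ".tif")))
  write_ground_truth(cohort[[i]]$gt, file.path(out, paste0(tag, "_gt")))
}
write.csv(manifest, file.path(out, "manifest.csv"), row.names = FALSE)

cat("Simulated", length(cohort), "sections into", out, "\n")
cat("Planted plaques per section:",
    paste(vapply(cohort, function(s) nrow(s$gt$plaques), 1L), collapse = " "),
    "\n")
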