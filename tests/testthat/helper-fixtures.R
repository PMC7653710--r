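# Shared fixture builders. All fixtures are generated in code, seeded.

# sparse, noise-free section: disjoint 30-um bands, so every planted object
# is recoverable exactly by the measurement chain
sparse_section_config <- function(seed) {
  section_config(field_size_um = c(500, 500), plaque_density = 16,
                 background_microglia_density = 8,
                 noise_sigma = 0, background_gradient_amp = 0,
                 plaque_margin_um = 65, microglia_min_gap_um = 12,
                 seed = seed)
}

# plaque-free field of isolated microglia for per-cell morphometry
microglia_field_config <- function(seed) {
  section_config(field_size_um = c(300, 300), plaque_density = 0,
                 background_microglia_density = 60,
                 noise_sigma = 0, background_gradient_amp = 0,
                 microglia_min_gap_um = 42, seed = seed)
}

# study conditions for the two-group comparison (control vs suppressed
# microglial clustering), on compact sections for replicated runs
power_config <- function(condition_factor = 1, seed = 1) {
  section_config(field_size_um = c(200, 200), plaque_density = 75,
                 microglia_per_plaque_mean = 8,
                 condition_factor = condition_factor, seed = seed)
}

# rasterised disk mask
disk_mask_fixture <- function(n, cy, cx, r) {
  m <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n)
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- TRUE
  m
}

# match each measured plaque to the nearest planted plaque (um coordinates)
match_gt_plaque <- function(meas_row, gt_plaques) {
  d <- sqrt((gt_plaques$y_um - meas_row$y_um)^2 +
            (gt_plaques$x_um - meas_row$x_um)^2)
  gt_plaques[which.min(d), , drop = FALSE]
}

# brute-force grayscale opening (erosion then dilation by explicit
# min/max over offsets) with the same disc brush the implementation uses
brute_opening <- function(img, radius) {
  brush <- EBImage::makeBrush(2 * radius + 1, "disc")
  off <- which(brush > 0, arr.ind = TRUE) - radius - 1
  nr <- nrow(img); nc <- ncol(img)
  er <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    src <- matrix(Inf, nr, nc)
    rs <- (1 + max(0, off[k, 1])):(nr + min(0, off[k, 1]))
    cs <- (1 + max(0, off[k, 2])):(nc + min(0, off[k, 2]))
    src[rs - off[k, 1], cs - off[k, 2]] <- img[rs, cs]
    er <- pmin(er, src)
  }
  di <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(off))) {
    src <- matrix(-Inf, nr, nc)
    rs <- (1 + max(0, off[k, 1])):(nr + min(0, off[k, 1]))
    cs <- (1 + max(0, off[k, 2])):(nc + min(0, off[k, 2]))
    src[rs - off[k, 1], cs - off[k, 2]] <- er[rs, cs]
    di <- pmax(di, src)
  }
  di
}
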