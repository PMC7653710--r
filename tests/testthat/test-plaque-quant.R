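test_that("plaque detection applies the equivalent-diameter filter", {
  expect_identical(detect_plaques(matrix(FALSE, 20, 20), 1), list())
  # rasterised disk of radius 10 px at 1 um/px: d within 5% of 20 um
  m <- disk_mask_fixture(41, 21, 21, 10)
  pl <- detect_plaques(m, 1)
  expect_length(pl, 1)
  expect_equal(pl[[1]]$diameter_um, 2 * sqrt(sum(m) / pi))
  expect_lt(abs(pl[[1]]$diameter_um - 20) / 20, 0.05)
  expect_false(pl[[1]]$clipped)
  # an 8-um disk is excluded by the 9.9-um counting rule
  m8 <- disk_mask_fixture(31, 16, 16, 4)
  expect_length(detect_plaques(m8, 1), 0)
  expect_length(detect_plaques(m8, 1, min_diameter_um = 5), 1)
})

test_that("plaque detection is translation-invariant", {
  set.seed(41)
  m <- matrix(FALSE, 80, 80)
  m[20:30, 15:28] <- matrix(runif(11 * 14) > 0.3, 11, 14)
  m[50:60, 50:62] <- matrix(runif(11 * 13) > 0.3, 11, 13)
  p0 <- detect_plaques(m, 1, min_diameter_um = 2)
  shifted <- matrix(FALSE, 80, 80)
  shifted[7:80, 5:80] <- m[1:74, 1:76]
  p1 <- detect_plaques(shifted, 1, min_diameter_um = 2)
  expect_equal(length(p0), length(p1))
  for (i in seq_along(p0)) {
    expect_equal(p1[[i]]$diameter_um, p0[[i]]$diameter_um)
    expect_equal(unname(p1[[i]]$centroid_um - p0[[i]]$centroid_um), c(6, 4))
  }
})

test_that("plaque burden is the plaque-positive ROI percentage", {
  roi <- disk_mask_fixture(50, 25, 25, 20)
  expect_equal(plaque_burden(roi, roi, 1)$burden_percent, 100)
  expect_equal(plaque_burden(matrix(FALSE, 50, 50), roi, 1)$burden_percent, 0)
  expect_error(plaque_burden(roi, matrix(FALSE, 50, 50), 1), "empty ROI")
  set.seed(13)
  for (i in 1:50) {
    pm <- matrix(runif(400) > 0.6, 20, 20)
    rm <- matrix(runif(400) > 0.3, 20, 20)
    if (!any(rm)) next
    b <- plaque_burden(pm, rm, 2)
    # brute-force loop oracle
    n_in <- 0; n_roi <- 0
    for (p in 1:400) {
      if (rm[p]) n_roi <- n_roi + 1
      if (rm[p] && pm[p]) n_in <- n_in + 1
    }
    expect_equal(b$burden_percent, 100 * n_in / n_roi)
    expect_equal(b$roi_area_um2, n_roi * 4)
  }
})

test_that("band mask is the open annulus within the band width", {
  m <- disk_mask_fixture(201, 101, 101, 40)  # r = 20 um at 0.5 um/px
  pl <- detect_plaques(m, 0.5)[[1]]
  b0 <- band_mask(pl, width_um = 0)
  expect_length(b0$pixels, 0)
  b <- band_mask(pl, width_um = 30)
  analytic <- pi * (50^2 - 20^2)
  expect_lt(abs(b$area_um2 - analytic) / analytic, 0.03)
  expect_true(b$clipped)  # 50-um outer radius exceeds the 100-px half-field
  # no overlap with the plaque interior; all pixels within the distance
  expect_length(intersect(b$pixels, pl$pixels), 0)
  rows <- ((b$pixels - 1) %% 201); cols <- ((b$pixels - 1) %/% 201)
  d <- sqrt((rows - 100)^2 + (cols - 100)^2) * 0.5
  expect_true(all(d <= 30 + 20 + 0.8))  # within outer radius + pixel slack
  # bands of two plaques are computed independently and may share pixels
  m2 <- matrix(FALSE, 120, 120)
  m2[disk_mask_fixture(120, 40, 60, 10)] <- TRUE
  m2[disk_mask_fixture(120, 80, 60, 10)] <- TRUE
  pls <- detect_plaques(m2, 1)
  b1 <- band_mask(pls[[1]], 30); b2 <- band_mask(pls[[2]], 30)
  expect_gt(length(intersect(b1$pixels, b2$pixels)), 0)
})

test_that("band quantification: saturation, emptiness, and component counting", {
  m <- disk_mask_fixture(101, 51, 51, 15)
  pl <- detect_plaques(m, 1)[[1]]
  b <- band_mask(pl, 10)
  img <- matrix(7, 101, 101)
  empty <- quantify_band(img, matrix(FALSE, 101, 101), pl, b)
  expect_equal(empty$area_in_band_um2, 0)
  expect_equal(empty$n_objects_band, 0)
  full <- matrix(TRUE, 101, 101)
  sat <- quantify_band(img, full, pl, b)
  expect_equal(sat$area_in_band_um2, b$area_um2)
  expect_equal(sat$area_in_plaque_um2, pl$area_um2)
  expect_equal(sat$mean_intensity_band, 7)
  # three small objects: two touching the band, one outside it
  mk <- matrix(FALSE, 101, 101)
  mk[51, 68:69] <- TRUE        # in band (distance ~17)
  mk[30:31, 51] <- TRUE        # in band (distance ~20)
  mk[5, 5] <- TRUE             # far outside
  q <- quantify_band(img, mk, pl, b)
  expect_equal(q$n_objects_band, 2)
})

test_that("plaque-microglia counting assigns within/around and resolves overlaps", {
  pls <- detect_plaques(disk_mask_fixture(150, 75, 75, 12), 1)
  bands <- lapply(pls, band_mask, width_um = 30)
  none <- count_plaque_microglia(data.frame(y_um = numeric(), x_um = numeric()),
                                 pls, bands, 1)
  expect_equal(none$n_total, 0L)
  som <- data.frame(y_um = c(74, 74, 100, 5), x_um = c(74, 95, 74, 5))
  ct <- count_plaque_microglia(som, pls, bands, 1)
  expect_equal(ct$n_within, 1L)   # centre soma
  expect_equal(ct$n_around, 2L)   # two in the band; far corner unassigned
  # a soma on the outline pixel counts as within
  edge_px <- pls[[1]]$outline[1]
  som_edge <- data.frame(y_um = (edge_px - 1) %% 150, x_um = (edge_px - 1) %/% 150)
  expect_equal(count_plaque_microglia(som_edge, pls, bands, 1)$n_within, 1L)
  # a soma in two bands goes to the nearer outline
  m2 <- matrix(FALSE, 160, 160)
  m2[disk_mask_fixture(160, 50, 80, 10)] <- TRUE
  m2[disk_mask_fixture(160, 110, 80, 10)] <- TRUE
  pl2 <- detect_plaques(m2, 1)
  bd2 <- lapply(pl2, band_mask, width_um = 30)
  som2 <- data.frame(y_um = 71, x_um = 79)  # 12 um from plaque 1, 30 from plaque 2
  ct2 <- count_plaque_microglia(som2, pl2, bd2, 1)
  expect_equal(ct2$n_around, c(1L, 0L))
})

test_that("diameter-neurite relation handles monotone, flat and tiny inputs", {
  d <- c(10, 15, 20, 30, 42)
  r <- diameter_neurite_relation(d, c(2, 5, 6, 11, 20))
  expect_equal(r$spearman_rho, 1)
  expect_gt(r$pearson_r, 0.9)
  rr <- suppressWarnings(diameter_neurite_relation(d, rep(4, 5)))
  expect_true(is.nan(rr$pearson_r))
  expect_warning(correlation(d, rep(4, 5)), "zero variance")
  expect_error(diameter_neurite_relation(c(10, 12), c(1, 2)), ">= 3")
})

test_that("within-area plus band-positive area never exceeds the region total", {
  s <- generate_section(sparse_section_config(19))
  q <- quantify_section(s$stack, exclude_clipped = FALSE)
  for (i in seq_len(nrow(q$band_quant))) {
    row <- q$band_quant[i, ]
    pl <- q$plaque_objects[[match(row$plaque_id,
                                  sapply(q$plaque_objects, `[[`, "id"))]]
    expect_lte(row$area_in_plaque_um2 + row$area_in_band_um2,
               pl$area_um2 + row$band_area_um2 + 1e-9)
  }
})
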