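test_that("identical config and seed give bit-identical stacks and ground truth", {
  cfg <- section_config(field_size_um = c(150, 150), plaque_density = 60,
                        diameter_max_um = 40, seed = 42)
  a <- generate_section(cfg)
  b <- generate_section(cfg)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$gt$plaques, b$gt$plaques)
  expect_identical(a$gt$microglia, b$gt$microglia)
  cfg2 <- cfg; cfg2$seed <- 43
  c2 <- generate_section(cfg2)
  expect_false(identical(a$stack$data, c2$stack$data))
})

test_that("zero plaque density leaves the plaque channel to background only", {
  cfg <- section_config(field_size_um = c(150, 150), plaque_density = 0,
                        background_microglia_density = 0,
                        diameter_max_um = 40, seed = 3)
  s <- generate_section(cfg)
  expect_equal(nrow(s$gt$plaques), 0)
  expect_false(any(s$gt$masks$plaque))
  # plaque channel holds only noise + gradient, bounded well below a plaque
  expect_lt(max(s$stack$data[, , , 1]), 60)
})

test_that("a forced plaque's neurites all lie inside its 30-um band", {
  forced <- data.frame(y_um = 60, x_um = 60, diameter_um = 30)
  cfg <- section_config(field_size_um = c(120, 120), pixel_size_um = 1,
                        diameter_max_um = 35, noise_sigma = 0,
                        background_gradient_amp = 0,
                        background_microglia_density = 0,
                        neurite_rate = c(alpha = 5, beta = 0),
                        forced_plaques = forced, seed = 9)
  s <- generate_section(cfg)
  expect_equal(nrow(s$gt$plaques), 1)
  # brute-force distances from the disk outline
  d_out <- sqrt((s$gt$neurites$y_um - 60)^2 + (s$gt$neurites$x_um - 60)^2) - 15
  expect_true(all(d_out > 0 & d_out <= 30))
  expect_equal(nrow(s$gt$neurites), s$gt$plaques$neurite_count[1])
  # counts follow Poisson(5): across seeds, the mean is near 5
  counts <- sapply(1:40, function(sd) {
    cfg$seed <- sd
    nrow(generate_section(cfg, render = FALSE)$gt$neurites)
  })
  expect_gt(mean(counts), 5 - 3 * sqrt(5 / 40))
  expect_lt(mean(counts), 5 + 3 * sqrt(5 / 40))
})

test_that("ground-truth object centres are foreground in the noise-free masks", {
  s <- generate_section(sparse_section_config(31))
  gt <- s$gt
  for (i in seq_len(nrow(gt$plaques))) {
    yi <- round(gt$plaques$y_um[i]) + 1; xi <- round(gt$plaques$x_um[i]) + 1
    expect_true(gt$masks$plaque[yi, xi])
  }
  for (g in gt$microglia)
    expect_true(gt$masks$microglia[round(g$y_um) + 1, round(g$x_um) + 1])
  for (i in seq_len(nrow(gt$neurites)))
    expect_true(gt$masks$neurite[round(gt$neurites$y_um[i]) + 1,
                                 round(gt$neurites$x_um[i]) + 1])
  if (nrow(gt$lysosomes))
    for (i in seq_len(nrow(gt$lysosomes)))
      expect_true(gt$masks$lysosome[round(gt$lysosomes$y_um[i]) + 1,
                                    round(gt$lysosomes$x_um[i]) + 1])
})

test_that("plaque-associated somata lie within the band; background cells beyond it", {
  s <- generate_section(sparse_section_config(8), render = FALSE)
  gt <- s$gt
  for (g in gt$microglia) {
    if (is.na(g$plaque_id)) {
      dmin <- if (nrow(gt$plaques)) min(
        sqrt((gt$plaques$y_um - g$y_um)^2 + (gt$plaques$x_um - g$x_um)^2) -
          gt$plaques$diameter_um / 2) else Inf
      expect_gt(dmin, 30)
    } else {
      p <- gt$plaques[gt$plaques$id == g$plaque_id, ]
      d_out <- sqrt((p$y_um - g$y_um)^2 + (p$x_um - g$x_um)^2) - p$diameter_um / 2
      expect_lte(d_out, 30)
    }
  }
})

test_that("cohorts use counter-derived sub-seeds and are reproducible", {
  c1 <- section_config(field_size_um = c(120, 120), diameter_max_um = 40,
                       plaque_density = 50, seed = 1)
  c2 <- c1; c2$condition_factor <- 0.5
  coh <- generate_cohort(c1, c2, 1, seed = 99)
  expect_length(coh, 2)
  expect_equal(sapply(coh, `[[`, "group"), c("control", "condition"))
  expect_false(identical(coh[[1]]$stack$data, coh[[2]]$stack$data))
  # member 2 reproducible in isolation from its derived sub-seed
  c2b <- c2; c2b$seed <- derive_seed(99, 2)
  solo <- generate_section(c2b)
  expect_identical(solo$stack$data, coh[[2]]$stack$data)
})

test_that("planted diameter-neurite correlation is positive with beta > 0", {
  # >= 200 planted plaques per seed, ground-truth fast path
  pos <- 0
  for (sd in 1:100) {
    cfg <- section_config(field_size_um = c(1000, 1000), plaque_density = 280,
                          plaque_margin_um = 2,
                          microglia_per_plaque_mean = 0,
                          background_microglia_density = 0, seed = sd)
    gt <- generate_section(cfg, render = FALSE)$gt
    expect_gte(nrow(gt$plaques), 200)
    r <- stats::cor(gt$plaques$diameter_um, gt$plaques$neurite_count)
    if (r > 0) pos <- pos + 1
  }
  expect_gte(pos, 99)
})

test_that("planted microglia-per-plaque means scale with the condition factor", {
  count_rate <- function(factor) {
    tot_mg <- 0; tot_pl <- 0; sd <- 0
    while (tot_pl < 1000) {
      sd <- sd + 1
      cfg <- section_config(field_size_um = c(600, 600), plaque_density = 30,
                            condition_factor = factor,
                            background_microglia_density = 0,
                            seed = 5000 + sd)
      gt <- generate_section(cfg, render = FALSE)$gt
      tot_pl <- tot_pl + nrow(gt$plaques)
      tot_mg <- tot_mg + sum(vapply(gt$microglia,
                                    function(m) !is.na(m$plaque_id), TRUE))
    }
    tot_mg / tot_pl
  }
  m1 <- count_rate(1)
  m06 <- count_rate(0.6)
  expect_lt(abs(m06 / m1 - 0.6), 0.05)
})

test_that("configs reject impossible geometry and negative rates", {
  expect_error(section_config(field_size_um = c(80, 80), diameter_max_um = 50),
               "twice the maximum")
  expect_error(section_config(plaque_density = -1), ">= 0")
  expect_error(section_config(diameter_min_um = 60, diameter_max_um = 50),
               "diameter_min_um")
  expect_error(section_config(pixel_size_um = 0), "pixel_size_um")
})
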