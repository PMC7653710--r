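# from-scratch balanced two-way ANOVA sums of squares (textbook cell-means
# decomposition), independent of the model-fitting code path
anova_ss_oracle <- function(y, a, b) {
  a <- factor(a); b <- factor(b)
  n <- table(a, b)[1, 1]
  gm <- mean(y)
  am <- tapply(y, a, mean); bm <- tapply(y, b, mean)
  cm <- tapply(y, interaction(a, b), mean)
  ss_a <- n * nlevels(b) * sum((am - gm)^2)
  ss_b <- n * nlevels(a) * sum((bm - gm)^2)
  ss_cells <- n * sum((cm - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_cells
  df_err <- length(y) - nlevels(a) * nlevels(b)
  list(F_a = (ss_a / (nlevels(a) - 1)) / (ss_err / df_err),
       F_b = (ss_b / (nlevels(b) - 1)) / (ss_err / df_err),
       F_ab = (ss_ab / ((nlevels(a) - 1) * (nlevels(b) - 1))) / (ss_err / df_err),
       ss = c(ss_a, ss_b, ss_ab), ss_err = ss_err, ss_tot = ss_tot)
}

test_that("two-way ANOVA F values match the from-scratch sums-of-squares oracle", {
  set.seed(201)
  for (i in 1:10) {
    a <- rep(rep(c("Aw", "A+"), each = 5), 2)
    b <- rep(c("STD", "TWD"), each = 10)
    y <- rnorm(20, mean = 10 + 2 * (a == "A+") + 1.5 * (b == "TWD") +
                 rnorm(1) * (a == "A+") * (b == "TWD"))
    res <- two_way_anova(y, a, b)
    orc <- anova_ss_oracle(y, a, b)
    expect_equal(res$F[res$effect == "A"], orc$F_a, tolerance = 1e-9)
    expect_equal(res$F[res$effect == "B"], orc$F_b, tolerance = 1e-9)
    expect_equal(res$F[res$effect == "A:B"], orc$F_ab, tolerance = 1e-9)
    # decomposition: SS_A + SS_B + SS_AB + SS_err = SS_total (balanced)
    expect_equal(sum(orc$ss) + orc$ss_err, orc$ss_tot, tolerance = 1e-9)
    expect_equal(sum(res$ss), sum(orc$ss), tolerance = 1e-9)
  }
})

test_that("two-way ANOVA degenerate designs are rejected; no-effect data give F = 0", {
  a <- rep(c("x", "y"), each = 4)
  b <- rep(c("u", "v"), 4)
  # identical cell means with within-cell noise: all F exactly 0
  y <- c(1, 3, 3, 1, 1, 3, 3, 1)  # every cell is {1, 3}, mean 2
  res <- two_way_anova(y, a, b)
  expect_equal(res$F, c(0, 0, 0), tolerance = 1e-12)
  # one observation per cell: zero error df
  expect_error(two_way_anova(c(1, 2, 3, 4), c(1, 1, 2, 2), c(1, 2, 1, 2)),
               "zero error")
  # empty cell
  expect_error(two_way_anova(1:6, c(1, 1, 1, 1, 2, 2), c(1, 1, 2, 2, 1, 1)),
               "empty design cell")
})

# full-enumeration null distribution of U for small samples
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  u_obs <- sum(rank(all_v)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_all <- apply(idx, 2, function(ii)
    sum(rank(all_v)[ii]) - n1 * (n1 + 1) / 2)
  mean_u <- n1 * n2 / 2
  mean(abs(u_all - mean_u) >= abs(u_obs - mean_u) - 1e-9)
}

test_that("Mann-Whitney: exact enumeration oracle, symmetry and U + U' identity", {
  # identical multisets: U = n1 n2 / 2
  x <- c(1, 2, 3, 4)
  expect_equal(mann_whitney(x, x)$value, 8)
  # all x below all y, n = 3 + 3: two-sided exact p = 2/20 = 0.1
  r <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_true(r$exact)
  expect_equal(r$p_value, 0.1)
  # seeded tie-free data match full enumeration to 1e-12
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(5, 0.5)
    r <- mann_whitney(x, y)
    expect_equal(r$p_value, mw_enum_p(x, y), tolerance = 1e-12)
    # U + U' = n1 n2
    expect_equal(r$value + mann_whitney(y, x)$value, 25)
  }
})

test_that("Kruskal-Wallis: tie-corrected H, chi-square p, z^2 link to Mann-Whitney", {
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$value, 0)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$p_value, 1)
  set.seed(41)
  g <- list(rnorm(12), rnorm(12, 1), rnorm(12, 2))
  kw <- kruskal_wallis(g)
  # brute-force rank computation
  v <- unlist(g); rk <- rank(v)
  ni <- lengths(g); N <- length(v)
  ri <- tapply(rk, rep(seq_along(g), ni), sum)
  h <- 12 / (N * (N + 1)) * sum(ri^2 / ni) - 3 * (N + 1)
  expect_equal(kw$value, h, tolerance = 1e-12)
  # two groups, no ties: H equals the squared MW normal deviate
  x <- rnorm(10); y <- rnorm(10, 0.8)
  kw2 <- kruskal_wallis(list(x, y))
  u <- mann_whitney(x, y)  # n = 20: normal approximation, no correction
  z2 <- stats::qnorm(u$p_value / 2)^2
  expect_equal(kw2$value, z2, tolerance = 1e-9)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
})

test_that("correlations: product-moment oracle, rank invariance, degenerate input", {
  x <- 1:10
  expect_equal(correlation(x, 2 * x + 1)$value, 1)
  expect_equal(correlation(x, 2 * x + 1, "spearman")$value, 1)
  # decreasing convex curve: rho = -1 but |r| < 1
  y <- exp(-x)
  expect_equal(correlation(x, y, "spearman")$value, -1)
  expect_gt(correlation(x, y)$value, -1)
  set.seed(51)
  a <- rnorm(20); b <- 0.6 * a + rnorm(20)
  r <- correlation(a, b)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r$value, oracle, tolerance = 1e-12)
  # spearman invariant under strictly monotone transforms
  expect_equal(correlation(exp(a), b, "spearman")$value,
               correlation(a, b, "spearman")$value)
  expect_warning(z <- correlation(rep(1, 5), 1:5), "zero variance")
  expect_true(is.nan(z$value))
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  r0 <- fisher_exact(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r0$odds_ratio, 1)
  expect_equal(r0$p_value, 1)
  # enumeration oracle with fixed margins
  fisher_enum <- function(tab, alternative) {
    m <- rowSums(tab); n <- colSums(tab)
    a_obs <- tab[1, 1]
    a_rng <- max(0, n[1] - m[2]):min(m[1], n[1])
    pr <- stats::dhyper(a_rng, m[1], m[2], n[1])
    p_obs <- stats::dhyper(a_obs, m[1], m[2], n[1])
    switch(alternative,
      two.sided = sum(pr[pr <= p_obs * (1 + 1e-7)]),
      greater = sum(pr[a_rng >= a_obs]),
      less = sum(pr[a_rng <= a_obs]))
  }
  tab <- matrix(c(20, 5, 4, 17), 2)  # fatty-liver evidence TWD vs STD
  for (alt in c("two.sided", "greater", "less")) {
    expect_equal(fisher_exact(tab, alt)$p_value, fisher_enum(tab, alt),
                 tolerance = 1e-12)
  }
  expect_equal(fisher_exact(tab)$odds_ratio, (20 * 17) / (4 * 5))
  # one-sided tails overlap at the observed table
  expect_gte(fisher_exact(tab, "greater")$p_value +
             fisher_exact(tab, "less")$p_value, 1)
  # zero cell: infinite sample odds ratio, finite enumeration p
  rz <- fisher_exact(matrix(c(3, 0, 0, 3), 2))
  expect_true(is.infinite(rz$odds_ratio))
  expect_equal(rz$p_value, fisher_enum(matrix(c(3, 0, 0, 3), 2), "two.sided"),
               tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("printed proportions use half-up rounding", {
  expect_equal(proportion(12, 24), 50)
  expect_equal(proportion(5, 22), 23)
  expect_equal(proportion(0, 7), 0)
  expect_equal(proportion(1, 8, 1), 12.5)
  expect_equal(proportion(1, 8), 13)  # 12.5 rounds up, not to even
  expect_error(proportion(3, 0), "> 0")
  expect_error(proportion(5, 4), "\\[0, n\\]")
})

test_that("response-concordance classification follows the Z-cutoff rule", {
  cl <- classify_response(c(3, 3, 1, 0, 3, -3), c(3, 0, 1, 3, -3, -3))
  expect_equal(as.character(cl$records$class),
               c("concordant", "discordant", "neither", "enhanced",
                 "neither", "concordant"))
  # z2 = z1: perfect correlation, no discordant genes
  z <- rnorm(100, sd = 2)
  cl2 <- classify_response(z, z)
  expect_equal(cl2$correlation, 1)
  expect_equal(unname(cl2$counts["discordant"]), 0L)
  # the four classes partition every record
  set.seed(61)
  z1 <- rnorm(500, sd = 2); z2 <- rnorm(500, sd = 2)
  cl3 <- classify_response(z1, z2)
  expect_equal(sum(cl3$counts), 500L)
  expect_false(any(is.na(cl3$records$class)))
})

test_that("2^-ddCt fold changes follow the closed form", {
  expect_equal(ddct_fold_change(20, 20, 20, 20), 1)
  expect_equal(ddct_fold_change(19, 20, 20, 20), 2)   # ddCt = -1
  expect_equal(ddct_fold_change(25, 20, 22, 20), 0.125)  # ddCt = 3
})
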