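#' Two-way factorial ANOVA
#'
#' Between-subject two-way ANOVA with interaction, the workhorse test for
#' diet-by-genotype designs. Sums of squares are Type II (via
#' \code{car::Anova}), which coincide with Type I and III on balanced
#' designs. Empty design cells or zero error degrees of freedom are errors.
#'
#' @param response numeric response vector.
#' @param factor_a,factor_b factors (or coercible), same length as response.
#' @return data frame, one row per effect (\code{A}, \code{B}, \code{A:B}):
#'   \code{effect}, \code{ss}, \code{df1}, \code{df2}, \code{F}, \code{p}.
#' @export
two_way_anova <- function(response, factor_a, factor_b) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(response) == length(a), length(a) == length(b))
  if (nlevels(a) < 2 || nlevels(b) < 2) stop("each factor needs >= 2 levels")
  if (any(table(a, b) == 0))
    stop("empty design cell: interaction is inestimable")
  fit <- stats::lm(response ~ a * b)
  if (stats::df.residual(fit) == 0)
    stop("zero error degrees of freedom (one observation per cell)")
  tab <- car::Anova(fit, type = 2)
  eff <- c("a", "b", "a:b")
  rows <- match(eff, rownames(tab))
  data.frame(effect = c("A", "B", "A:B"),
             ss = tab$`Sum Sq`[rows],
             df1 = tab$Df[rows],
             df2 = stats::df.residual(fit),
             F = tab$`F value`[rows],
             p = tab$`Pr(>F)`[rows])
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples; U uses mid-ranks for
#' ties. The p-value is exact (full null enumeration) when the combined
#' sample size is at most 14 and there are no ties, otherwise the normal
#' approximation with tie correction is used.
#'
#' @param x,y numeric samples.
#' @param alternative \code{"two.sided"}, \code{"less"} or \code{"greater"}.
#' @return list: \code{statistic} ("U"), \code{value}, \code{p_value},
#'   \code{exact}.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 14) && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = FALSE))
  list(statistic = "U", value = unname(wt$statistic), p_value = wt$p.value,
       exact = exact, n1 = length(x), n2 = length(y))
}

#' Kruskal-Wallis H test
#'
#' @param groups list of numeric vectors (>= 2 groups, each nonempty).
#' @return list: \code{statistic} ("H"), \code{value}, \code{df},
#'   \code{p_value}. All-identical data give H = 0, p = 1.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) == 0)) stop("each group must be nonempty")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1)
    return(list(statistic = "H", value = 0, df = length(groups) - 1,
                p_value = 1))
  kt <- stats::kruskal.test(vals, factor(rep(seq_along(groups), lengths(groups))))
  list(statistic = "H", value = unname(kt$statistic),
       df = unname(kt$parameter), p_value = kt$p.value)
}

#' Pearson or Spearman correlation
#'
#' Pearson r is the product-moment coefficient with the usual t-based
#' p-value; Spearman rho is Pearson on mid-rank-transformed data, also with
#' a t-approximation p-value. Zero variance in either variable gives NaN
#' with a warning rather than an error.
#'
#' @param x,y numeric vectors, length >= 3, finite.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list: \code{statistic} ("r" or "rho"), \code{value},
#'   \code{p_value}, \code{n}.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need n >= 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(statistic = if (method == "pearson") "r" else "rho",
                value = NaN, p_value = NaN, n = n))
  }
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(statistic = if (method == "pearson") "r" else "rho",
       value = r, p_value = p, n = n)
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional (hypergeometric) p-value; the reported odds ratio is the
#' sample odds ratio ad/bc (infinite when a zero cell makes it so), not the
#' conditional MLE. The two-sided p sums the probabilities of tables at
#' most as probable as the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative \code{"two.sided"}, \code{"less"} or \code{"greater"}
#'   (one-tailed variants per the enrichment-testing convention).
#' @return list: \code{odds_ratio}, \code{p_value}, \code{alternative}.
#' @export
fisher_exact <- function(tab, alternative = "two.sided") {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != floor(tab))) stop("counts must be non-negative integers")
  ft <- stats::fisher.test(tab, alternative = alternative)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p_value = ft$p.value, alternative = alternative)
}

#' Printed proportion
#'
#' \code{100 k / n}, rounded half-up to \code{digits} decimals — the
#' convention behind printed percentages like 5/22 = 23\%.
#'
#' @param k numerator count, \code{0 <= k <= n}.
#' @param n denominator count, \code{> 0}.
#' @param digits decimals (default 0).
#' @return percentage.
#' @export
proportion <- function(k, n, digits = 0) {
  if (n <= 0) stop("n must be > 0")
  if (k < 0 || k > n) stop("k must be in [0, n]")
  round_half_up(100 * k / n, digits)
}

#' Classify paired Z statistics by response concordance
#'
#' Given per-gene Z statistics for a response under two conditions (e.g.
#' standard diet vs Western diet), classifies each gene:
#' \emph{concordant} when both exceed the cutoff in absolute value with the
#' same sign; \emph{discordant} when the first exceeds the cutoff but the
#' second does not; \emph{enhanced} for the mirror case (second only);
#' \emph{neither} otherwise. Also returns the genome-wide Pearson
#' correlation of the two Z vectors.
#'
#' @param z1,z2 paired finite numeric vectors.
#' @param cutoff absolute-Z cutoff (default 2.5).
#' @return list: \code{records} (data frame with \code{z1}, \code{z2},
#'   \code{class}), \code{correlation}, \code{counts} (per class).
#' @export
classify_response <- function(z1, z2, cutoff = 2.5) {
  stopifnot(length(z1) == length(z2), all(is.finite(z1)), all(is.finite(z2)))
  big1 <- abs(z1) > cutoff
  big2 <- abs(z2) > cutoff
  cls <- rep("neither", length(z1))
  cls[big1 & big2 & sign(z1) == sign(z2)] <- "concordant"
  cls[big1 & !big2] <- "discordant"
  cls[!big1 & big2] <- "enhanced"
  cls <- factor(cls, levels = c("concordant", "discordant", "enhanced", "neither"))
  corr <- if (length(z1) >= 3 && stats::sd(z1) > 0 && stats::sd(z2) > 0)
    stats::cor(z1, z2) else NaN
  list(records = data.frame(z1 = z1, z2 = z2, class = cls),
       correlation = corr, counts = table(cls), cutoff = cutoff)
}

#' Relative qPCR expression by the 2^-ddCt method
#'
#' \code{ddCt = (Ct_target_sample - Ct_ref_sample) -
#' (Ct_target_control - Ct_ref_control)}; fold change is \code{2^-ddCt}.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_control,ct_ref_control
#'   finite Ct values (vectors recycle in the usual way).
#' @return fold change.
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_control, ct_ref_control) {
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Thin wrapper around \code{p.adjust(method = "BH")} for the transcriptomic
#' path, where discovery lists are FDR-controlled.
#'
#' @param p vector of p-values.
#' @return adjusted p-values.
#' @export
adjust_fdr <- function(p) stats::p.adjust(p, method = "BH")
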