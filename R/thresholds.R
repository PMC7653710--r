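#' Automatic histogram thresholding
#'
#' Computes a global intensity threshold with one of the four classical
#' histogram algorithms used for fluorescence segmentation: Otsu
#' (between-class variance), Li (minimum cross-entropy), Intermodes
#' (iterated histogram smoothing to bimodality) and Moments (Tsai
#' moment-preserving). The foreground rule is strictly greater-than:
#' a pixel is foreground iff \code{pixel > t}. This convention is used
#' everywhere in the package.
#'
#' The histogram uses 8-bit semantics: images whose values are integers in
#' [0, 255] are binned at the 256 integer levels; any other image is binned
#' into 256 uniform bins over its observed range, with each bin represented
#' by its centre. Ties in the Otsu criterion are broken toward the smallest
#' threshold.
#'
#' @param image numeric matrix of finite, non-negative intensities.
#' @param method one of \code{"otsu"}, \code{"li"}, \code{"intermodes"},
#'   \code{"moments"}.
#' @param n_bins number of histogram bins for non 8-bit data (default 256).
#' @param max_iter iteration cap for the Li fixed point and the Intermodes
#'   smoothing loop.
#' @return an object of class \code{threshold_result}: a list with
#'   \code{method}, \code{threshold}, \code{levels} (bin representative
#'   intensities), \code{counts}, and method-specific diagnostics
#'   (\code{z0}, \code{z1}, \code{p0} for moments; \code{iterations} for li;
#'   \code{smoothing_passes} and \code{modes} for intermodes).
#' @export
auto_threshold <- function(image, method = c("otsu", "li", "intermodes", "moments"),
                           n_bins = 256L, max_iter = 10000L) {
  method <- match.arg(method)
  x <- as.numeric(image)
  if (!all(is.finite(x))) stop("image contains non-finite intensities")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("degenerate histogram: image is constant")

  h <- intensity_histogram(x, n_bins)
  t <- switch(method,
    otsu       = otsu_threshold(h),
    li         = li_threshold(h, max_iter = max_iter),
    intermodes = intermodes_threshold(h, max_iter = max_iter),
    moments    = moments_threshold(h)
  )
  res <- c(list(method = method), t, list(levels = h$levels, counts = h$counts))
  class(res) <- "threshold_result"
  res
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> method=%s threshold=%.6g (rule: pixel > t)\n",
              x$method, x$threshold))
  invisible(x)
}

# Histogram with 8-bit semantics: integer data in [0,255] is binned at the
# 256 integer levels, otherwise 256 uniform bins over the observed range.
intensity_histogram <- function(x, n_bins = 256L) {
  is8bit <- all(x >= 0 & x <= 255) && all(x == floor(x))
  if (is8bit) {
    counts <- tabulate(as.integer(x) + 1L, nbins = 256L)
    list(levels = 0:255, counts = counts)
  } else {
    rng <- range(x)
    width <- diff(rng) / n_bins
    idx <- pmin(floor((x - rng[1]) / width), n_bins - 1)
    counts <- tabulate(as.integer(idx) + 1L, nbins = n_bins)
    list(levels = rng[1] + (seq_len(n_bins) - 0.5) * width, counts = counts)
  }
}

# Otsu (1979): threshold maximising between-class variance; smallest
# maximiser on ties. Candidates are splits with both classes nonempty.
otsu_threshold <- function(h) {
  p <- h$counts / sum(h$counts)
  v <- h$levels
  w0 <- cumsum(p)
  mu <- cumsum(p * v)
  mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, length(v))
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)  # first index among exact ties = smallest t
  list(threshold = v[k], between_class_variance = sigma_b[k], bin_index = k)
}

# Li & Lee / Li & Tam minimum cross-entropy: fixed point of
# t <- (mu_fg - mu_bg) / (log mu_fg - log mu_bg), class means weighted by the
# histogram. Intensities are shifted to be strictly positive if needed; the
# shift is removed from the returned threshold.
li_threshold <- function(h, tol = 1e-6, max_iter = 10000L) {
  v <- h$levels
  w <- h$counts / sum(h$counts)
  shift <- if (min(v[w > 0]) <= 0) 1 - min(v[w > 0]) else 0
  vs <- v + shift
  t <- sum(w * vs)  # start at the global mean
  it <- 0L
  repeat {
    it <- it + 1L
    bg <- vs <= t
    mb <- sum(w[bg] * vs[bg]) / sum(w[bg])
    mf <- sum(w[!bg] * vs[!bg]) / sum(w[!bg])
    if (!is.finite(mb) || !is.finite(mf)) break
    t_new <- (mf - mb) / (log(mf) - log(mb))
    # stop on a stable class split: the same background set under t_new
    # reproduces t_new, so the returned value is an exact fixed point
    if (identical(vs <= t_new, bg)) { t <- t_new; break }
    t <- t_new
    if (it >= max_iter) stop("li threshold did not converge")
  }
  list(threshold = t - shift, iterations = it, shift = shift)
}

# Prewitt & Mendelsohn intermodes: smooth the histogram with an iterated
# 3-bin running mean until exactly two local modes remain; threshold is the
# level midway between them.
intermodes_threshold <- function(h, max_iter = 10000L) {
  y <- as.numeric(h$counts)
  n <- length(y)
  passes <- 0L
  repeat {
    m <- local_modes(y)
    if (length(m) == 2L) break
    if (length(m) < 2L)
      stop("intermodes: histogram became unimodal before reaching two modes")
    passes <- passes + 1L
    if (passes > max_iter)
      stop("intermodes: histogram failed to become bimodal within ",
           max_iter, " smoothing passes")
    y <- (c(y[1], y[-n]) + y + c(y[-1], y[n])) / 3
  }
  k <- floor((m[1] + m[2]) / 2)
  list(threshold = h$levels[k], smoothing_passes = passes,
       modes = h$levels[m], bin_index = k)
}

local_modes <- function(y) {
  n <- length(y)
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  which(y > left & y >= right & y > 0)
}

# Tsai (1985) moment-preserving threshold: find the two-level image
# (fractions p0/1-p0 at grey values z0/z1) preserving the first three raw
# moments, then split the histogram at the p0 quantile.
moments_threshold <- function(h) {
  w <- h$counts / sum(h$counts)
  v <- h$levels
  m1 <- sum(w * v); m2 <- sum(w * v^2); m3 <- sum(w * v^3)
  cd <- m2 - m1^2
  if (cd <= 0) stop("degenerate histogram: zero variance")
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) stop("moments: complex roots (pathological histogram)")
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)
  cw <- cumsum(w)
  k <- which(cw >= p0)[1]
  list(threshold = v[k], z0 = z0, z1 = z1, p0 = p0, bin_index = k)
}
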