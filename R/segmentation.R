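#' Multi-channel image stack
#'
#' Container for a multi-channel (optionally z-stacked) fluorescence section.
#' Data are stored as a 4-D array \code{[y, x, z, channel]}; a 3-D array is
#' interpreted as a single z-slice per channel and a matrix as one channel,
#' one slice. Pixel centres sit at \code{(i - 1) * pixel_size_um} micrometres
#' so pixel (1,1) is the origin.
#'
#' @param data numeric array: \code{[y, x]}, \code{[y, x, channel]} or
#'   \code{[y, x, z, channel]}; finite, non-negative intensities.
#' @param pixel_size_um in-plane pixel size, micrometres per pixel.
#' @param channel_roles character vector, one role per channel, from
#'   \code{c("plaque", "microglia", "lysosome", "neurite", "other")}.
#' @param provenance free-text provenance tag.
#' @return an object of class \code{image_stack}.
#' @export
image_stack <- function(data, pixel_size_um, channel_roles,
                        provenance = "unspecified") {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  if (length(dim(data)) != 4L) stop("data must be a 2-, 3- or 4-D array")
  if (!all(is.finite(data)) || any(data < 0))
    stop("intensities must be finite and >= 0")
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  nch <- dim(data)[4]
  if (length(channel_roles) != nch)
    stop("channel_roles must name each of the ", nch, " channels")
  ok <- c("plaque", "microglia", "lysosome", "neurite", "other")
  if (!all(channel_roles %in% ok))
    stop("channel roles must be in {", paste(ok, collapse = ", "), "}")
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 channel_roles = channel_roles, provenance = provenance),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d px, %d z-slice(s), %d channel(s) [%s], %.3g um/px\n",
              d[1], d[2], d[3], d[4], paste(x$channel_roles, collapse = ", "),
              x$pixel_size_um))
  invisible(x)
}

get_channel <- function(stack, role) {
  i <- which(stack$channel_roles == role)
  if (length(i) == 0L) stop("stack has no channel with role '", role, "'")
  stack$data[, , , i[1], drop = FALSE]
}

#' Maximum intensity projection
#'
#' Collapses the z dimension of each channel by the per-pixel maximum.
#' A single-slice stack is returned unchanged (as 2-D images).
#'
#' @param stack an \code{image_stack}.
#' @return named list of 2-D matrices, one per channel, named by role.
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  out <- vector("list", d[4])
  for (ch in seq_len(d[4])) {
    m <- stack$data[, , 1L, ch]
    if (d[3] > 1L) for (z in 2:d[3]) m <- pmax(m, stack$data[, , z, ch])
    out[[ch]] <- m
  }
  names(out) <- stack$channel_roles
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale morphological opening of the
#' image with a flat disk of the given radius (the classical rolling-ball
#' approximation) and subtracts it, clipping at zero. Adding a constant to
#' the image does not change the output.
#'
#' @param image 2-D numeric matrix.
#' @param ball_radius_px structuring-disk radius in pixels (>= 1).
#' @return background-subtracted matrix, same dimensions.
#' @export
subtract_background <- function(image, ball_radius_px = 25) {
  if (ball_radius_px < 1) stop("ball_radius_px must be >= 1")
  if (2 * ball_radius_px + 1 > min(dim(image)))
    stop("ball radius larger than the image: radius ", ball_radius_px,
         " needs at least ", 2 * ball_radius_px + 1, " px in each dimension")
  brush <- EBImage::makeBrush(2 * as.integer(ball_radius_px) + 1L, shape = "disc")
  # EBImage grayscale morphology clips to [0, 1]: rescale around the call
  scale <- max(max(image), 1)
  bg <- EBImage::imageData(EBImage::opening(image / scale, brush)) * scale
  pmax(image - bg, 0)
}

#' Gaussian smoothing with reflective boundaries
#'
#' Separable discrete Gaussian convolution; the kernel is truncated at
#' 3 sigma and renormalised, and the image is padded by mirror reflection
#' (edge pixel included). \code{sigma_px = 0} returns the input unchanged.
#'
#' @param image 2-D numeric matrix.
#' @param sigma_px Gaussian standard deviation in pixels (>= 0).
#' @return smoothed matrix, same dimensions.
#' @export
gaussian_smooth <- function(image, sigma_px = 2) {
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  if (sigma_px == 0) return(image)
  r <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  sm <- convolve_1d_rows(image, k, r)
  t(convolve_1d_rows(t(sm), k, r))
}

# Convolve each row with kernel k (length 2r+1), mirror-reflect padding.
convolve_1d_rows <- function(m, k, r) {
  n <- ncol(m)
  idx <- c(pmin(r:1, n), 1:n, pmax(n - (1:r) + 1, 1))
  pad <- m[, idx, drop = FALSE]
  out <- matrix(0, nrow(m), n)
  for (j in seq_along(k)) out <- out + k[j] * pad[, j:(j + n - 1), drop = FALSE]
  out
}

#' Segment one channel of a stack
#'
#' The standard preprocessing chain: maximum projection, rolling-ball
#' background subtraction, Gaussian smoothing, then automatic histogram
#' thresholding. Default threshold method per role follows the staining
#' conventions this pipeline quantifies: Otsu for the plaque dye, Intermodes
#' for the neurite marker, Moments for the microglial and lysosomal markers;
#' Li is available for the morphometry path.
#'
#' @param stack an \code{image_stack}.
#' @param channel_role which channel to segment.
#' @param method threshold method; \code{NULL} selects the per-role default.
#' @param ball_radius_px rolling-ball radius (pixels); \code{0} disables
#'   background subtraction.
#' @param sigma_px Gaussian sigma (pixels); \code{0} disables smoothing.
#' @return list with \code{mask} (logical matrix), \code{threshold}
#'   (a \code{threshold_result}) and \code{params} (full provenance).
#' @export
segment_channel <- function(stack, channel_role, method = NULL,
                            ball_radius_px = 25, sigma_px = 2) {
  defaults <- c(plaque = "otsu", neurite = "intermodes",
                microglia = "moments", lysosome = "moments", other = "otsu")
  if (is.null(method)) method <- defaults[[channel_role]]
  img <- max_projection(stack)[[channel_role]]
  if (is.null(img)) stop("stack has no channel with role '", channel_role, "'")
  if (ball_radius_px > 0) img <- subtract_background(img, ball_radius_px)
  if (sigma_px > 0) img <- gaussian_smooth(img, sigma_px)
  th <- auto_threshold(img, method)
  list(mask = img > th$threshold, threshold = th, image = img,
       params = list(channel_role = channel_role, method = method,
                     ball_radius_px = ball_radius_px, sigma_px = sigma_px,
                     pixel_size_um = stack$pixel_size_um))
}
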