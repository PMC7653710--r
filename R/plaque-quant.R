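#' Detect amyloid plaques in a binary mask
#'
#' Extracts 8-connected components of a segmented plaque mask, converts them
#' to physical units and discards components whose equivalent diameter
#' \eqn{d = 2\sqrt{A/\pi}} does not exceed the minimum — the conventional
#' counting rule keeps plaques over 9.9 micrometres in diameter. Components
#' touching the image border are flagged as clipped.
#'
#' @param plaque_mask logical matrix (foreground = plaque).
#' @param pixel_size_um micrometres per pixel.
#' @param min_diameter_um plaques with equivalent diameter less than or equal
#'   to this are discarded (default 9.9).
#' @return list of \code{plaque} objects, ordered by centroid (row-major);
#'   each has \code{id}, \code{pixels} (linear indices), \code{area_um2},
#'   \code{diameter_um}, \code{centroid_um} (y, x), \code{outline}
#'   (linear indices of boundary pixels), \code{clipped}, \code{dim}.
#'   An empty mask gives an empty list.
#' @export
detect_plaques <- function(plaque_mask, pixel_size_um, min_diameter_um = 9.9) {
  stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
  lab <- label_components(plaque_mask, connectivity = 8)
  st <- component_stats(lab)
  if (nrow(st) == 0) return(list())
  px_area <- pixel_size_um^2
  st$area_um2 <- st$n_pixels * px_area
  st$diameter_um <- 2 * sqrt(st$area_um2 / pi)
  st <- st[st$diameter_um > min_diameter_um, , drop = FALSE]
  if (nrow(st) == 0) return(list())
  # deterministic ordering: centroid row-major (y, then x)
  st <- st[order(st$cy, st$cx), , drop = FALSE]
  nr <- nrow(plaque_mask); nc <- ncol(plaque_mask)
  interior <- interior_mask(lab)
  out <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    l <- st$label[i]
    pix <- which(lab == l)
    rows <- ((pix - 1) %% nr) + 1
    cols <- ((pix - 1) %/% nr) + 1
    out[[i]] <- structure(list(
      id = i,
      pixels = pix,
      area_um2 = st$area_um2[i],
      diameter_um = st$diameter_um[i],
      centroid_um = c(y = (st$cy[i] - 1) * pixel_size_um,
                      x = (st$cx[i] - 1) * pixel_size_um),
      outline = pix[!interior[pix]],
      clipped = any(rows == 1 | rows == nr | cols == 1 | cols == nc),
      dim = c(nr, nc),
      pixel_size_um = pixel_size_um), class = "plaque")
  }
  out
}

# pixels whose 4-neighbours are all foreground of the same label (non-border)
interior_mask <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  same <- (pad[1:nr, 2:(nc + 1)] == ctr) & (pad[3:(nr + 2), 2:(nc + 1)] == ctr) &
          (pad[2:(nr + 1), 1:nc] == ctr) & (pad[2:(nr + 1), 3:(nc + 2)] == ctr)
  same & ctr > 0
}

#' Summarise detected plaques as a data frame
#' @param plaques list returned by \code{\link{detect_plaques}}.
#' @return data frame with one row per plaque.
#' @export
plaques_df <- function(plaques) {
  if (length(plaques) == 0)
    return(data.frame(id = integer(), area_um2 = numeric(),
                      diameter_um = numeric(), y_um = numeric(),
                      x_um = numeric(), clipped = logical()))
  data.frame(
    id = vapply(plaques, `[[`, 1L, "id"),
    area_um2 = vapply(plaques, `[[`, 1, "area_um2"),
    diameter_um = vapply(plaques, `[[`, 1, "diameter_um"),
    y_um = vapply(plaques, function(p) p$centroid_um[["y"]], 1),
    x_um = vapply(plaques, function(p) p$centroid_um[["x"]], 1),
    clipped = vapply(plaques, `[[`, TRUE, "clipped"))
}

#' Plaque burden of a region of interest
#'
#' Burden is the plaque-positive fraction of the ROI, expressed as a
#' percentage: \code{100 * |plaque & roi| / |roi|}.
#'
#' @param plaque_mask,roi_mask logical matrices of identical dimensions.
#' @param pixel_size_um micrometres per pixel.
#' @return list with \code{roi_area_um2}, \code{plaque_area_um2},
#'   \code{burden_percent}.
#' @export
plaque_burden <- function(plaque_mask, roi_mask, pixel_size_um) {
  stopifnot(identical(dim(plaque_mask), dim(roi_mask)))
  n_roi <- sum(roi_mask != 0)
  if (n_roi == 0) stop("empty ROI")
  n_in <- sum(plaque_mask != 0 & roi_mask != 0)
  px2 <- pixel_size_um^2
  list(roi_area_um2 = n_roi * px2, plaque_area_um2 = n_in * px2,
       burden_percent = 100 * n_in / n_roi)
}

#' Proximity band (annulus) around a plaque
#'
#' Pixels whose Euclidean distance to the plaque is in \code{(0, width_um]}:
#' the band around the outline, excluding the plaque interior. Bands of
#' different plaques are computed independently, so a pixel may belong to
#' several bands. A band reaching the image border is flagged clipped.
#'
#' @param plaque a \code{plaque} object.
#' @param width_um band width in micrometres (default 30).
#' @param image_shape \code{c(nrow, ncol)}; defaults to the plaque's own.
#' @param pixel_size_um micrometres per pixel; defaults to the plaque's own.
#' @return list with \code{pixels} (linear indices), \code{area_um2},
#'   \code{clipped}, \code{width_um}.
#' @export
band_mask <- function(plaque, width_um = 30, image_shape = plaque$dim,
                      pixel_size_um = plaque$pixel_size_um) {
  if (width_um < 0) stop("width_um must be >= 0")
  nr <- image_shape[1]; nc <- image_shape[2]
  if (width_um == 0)
    return(list(pixels = integer(), area_um2 = 0, clipped = FALSE,
                width_um = 0))
  m <- matrix(0, nr, nc)
  m[plaque$pixels] <- 1
  d <- EBImage::imageData(EBImage::distmap(1 - m)) * pixel_size_um
  sel <- which(d > 0 & d <= width_um)
  rows <- ((sel - 1) %% nr) + 1
  cols <- ((sel - 1) %/% nr) + 1
  list(pixels = sel, area_um2 = length(sel) * pixel_size_um^2,
       clipped = any(rows == 1 | rows == nr | cols == 1 | cols == nc),
       width_um = width_um)
}

#' Quantify a marker inside a plaque and in its proximity band
#'
#' Positive area is the marker-mask area intersected with each region; mean
#' intensity is averaged over all band pixels (not only marker-positive
#' ones); the object count is the number of 8-connected marker components
#' with at least one pixel in the band.
#'
#' @param marker_image numeric matrix of marker intensities.
#' @param marker_mask logical matrix (segmented marker).
#' @param plaque a \code{plaque}.
#' @param band result of \code{\link{band_mask}} for that plaque.
#' @param pixel_size_um micrometres per pixel.
#' @param marker_labels optional precomputed label matrix of
#'   \code{marker_mask} (8-connected), to avoid relabelling per plaque.
#' @return list with \code{plaque_id}, \code{area_in_plaque_um2},
#'   \code{area_in_band_um2}, \code{mean_intensity_band},
#'   \code{n_objects_band}, \code{band_area_um2}, \code{band_clipped}.
#' @export
quantify_band <- function(marker_image, marker_mask, plaque, band,
                          pixel_size_um = plaque$pixel_size_um,
                          marker_labels = NULL) {
  px2 <- pixel_size_um^2
  lab <- if (is.null(marker_labels))
    label_components(marker_mask, connectivity = 8) else marker_labels
  in_band <- lab[band$pixels]
  list(plaque_id = plaque$id,
       area_in_plaque_um2 = sum(marker_mask[plaque$pixels] != 0) * px2,
       area_in_band_um2 = sum(marker_mask[band$pixels] != 0) * px2,
       mean_intensity_band = if (length(band$pixels))
         mean(marker_image[band$pixels]) else NaN,
       n_objects_band = length(unique(in_band[in_band > 0])),
       band_area_um2 = band$area_um2,
       band_clipped = band$clipped)
}

#' Detect microglial somata
#'
#' Somata are the bodies that survive a grayscale opening removing the thin
#' processes. Touching somata are separated by a watershed of the distance
#' map of the opened mask; blobs count as somata when their area is at
#' least \code{soma_min_area_um2} and they are compact (area at least
#' \code{min_compactness} of the circumscribed circle around the
#' centroid), the operational proxy for a clearly visible soma. The
#' compactness gate rejects the elongated remnants that crossing processes
#' leave in the opened mask while keeping disk-like cell bodies.
#'
#' @param microglia_mask logical matrix.
#' @param pixel_size_um micrometres per pixel.
#' @param soma_min_area_um2 minimum soma area (default 20).
#' @param opening_radius_px disk radius of the process-removing opening
#'   (default 3: large enough that process remnants never masquerade as
#'   somata, small enough that an 8 um soma survives).
#' @param min_compactness minimum ratio of blob area to the area of the
#'   circle through its farthest pixel (1 for a perfect disk; default 0.4).
#' @return data frame: \code{id}, \code{y_um}, \code{x_um}, \code{area_um2}.
#' @export
detect_somata <- function(microglia_mask, pixel_size_um,
                          soma_min_area_um2 = 20, opening_radius_px = 3,
                          min_compactness = 0.4) {
  lab <- soma_labels(microglia_mask, opening_radius_px)
  st <- soma_candidates(lab, pixel_size_um)
  st <- st[st$area_um2 >= soma_min_area_um2 &
           st$compactness >= min_compactness, , drop = FALSE]
  st <- st[order(st$cy, st$cx), , drop = FALSE]
  data.frame(id = seq_len(nrow(st)),
             y_um = (st$cy - 1) * pixel_size_um,
             x_um = (st$cx - 1) * pixel_size_um,
             area_um2 = st$area_um2)
}

#' @rdname detect_somata
#' @return \code{soma_mask} returns the logical mask of accepted somata.
#' @export
soma_mask <- function(microglia_mask, pixel_size_um,
                      soma_min_area_um2 = 20, opening_radius_px = 3,
                      min_compactness = 0.4) {
  lab <- soma_labels(microglia_mask, opening_radius_px)
  st <- soma_candidates(lab, pixel_size_um)
  keep <- st$label[st$area_um2 >= soma_min_area_um2 &
                   st$compactness >= min_compactness]
  matrix(lab %in% keep & lab > 0, nrow(lab), ncol(lab))
}

# per-candidate area and compactness (area over circumscribed-circle area)
soma_candidates <- function(lab, pixel_size_um) {
  st <- component_stats(lab)
  st$area_um2 <- st$n_pixels * pixel_size_um^2
  st$compactness <- NA_real_
  if (nrow(st)) {
    idx <- which(lab > 0)
    l <- lab[idx]
    rows <- ((idx - 1) %% nrow(lab)) + 1
    cols <- ((idx - 1) %/% nrow(lab)) + 1
    d2 <- (rows - st$cy[l])^2 + (cols - st$cx[l])^2
    dmax2 <- tapply(d2, l, max)
    st$compactness <- st$n_pixels / (pi * pmax(dmax2[as.character(st$label)], 1))
  }
  st
}

# opened mask, then watershed on the distance map to split touching somata
soma_labels <- function(microglia_mask, opening_radius_px = 3) {
  m <- matrix(as.numeric(microglia_mask != 0), nrow(microglia_mask),
              ncol(microglia_mask))
  op <- EBImage::imageData(EBImage::opening(
    m, EBImage::makeBrush(2L * as.integer(opening_radius_px) + 1L, "disc")))
  if (!any(op > 0.5)) return(matrix(0L, nrow(m), ncol(m)))
  d <- EBImage::distmap(op)
  w <- EBImage::imageData(EBImage::watershed(d, tolerance = 1, ext = 1))
  lab <- matrix(as.integer(w), nrow(m), ncol(m))
  relabel_scan_order(lab)
}

#' Count microglia within and around each plaque
#'
#' Assigns each soma centroid to a plaque: inside the plaque mask (outline
#' pixels included) counts as within; otherwise, a soma in one or more
#' proximity bands counts as around, assigned to the plaque with the nearest
#' outline (ties to the lower plaque id); somata in no band are unassigned.
#'
#' @param somata data frame from \code{\link{detect_somata}} (or any frame
#'   with \code{y_um}, \code{x_um}).
#' @param plaques list of \code{plaque} objects.
#' @param bands list of band results, parallel to \code{plaques}.
#' @param pixel_size_um micrometres per pixel.
#' @return data frame, one row per plaque: \code{plaque_id}, \code{n_within},
#'   \code{n_around}, \code{n_total}.
#' @export
count_plaque_microglia <- function(somata, plaques, bands,
                                   pixel_size_um = plaques[[1]]$pixel_size_um) {
  n_within <- integer(length(plaques))
  n_around <- integer(length(plaques))
  if (nrow(somata) > 0 && length(plaques) > 0) {
    nr <- plaques[[1]]$dim[1]
    ri <- round(somata$y_um / pixel_size_um) + 1
    ci <- round(somata$x_um / pixel_size_um) + 1
    ri <- pmin(pmax(ri, 1), nr); ci <- pmin(pmax(ci, 1), plaques[[1]]$dim[2])
    lin <- (ci - 1) * nr + ri
    for (s in seq_len(nrow(somata))) {
      inside <- which(vapply(plaques, function(p) lin[s] %in% p$pixels, TRUE))
      if (length(inside) > 0) {
        n_within[inside[1]] <- n_within[inside[1]] + 1L
        next
      }
      in_band <- which(vapply(bands, function(b) lin[s] %in% b$pixels, TRUE))
      if (length(in_band) == 0) next
      if (length(in_band) == 1) {
        n_around[in_band] <- n_around[in_band] + 1L
      } else {
        d <- vapply(in_band, function(i)
          point_to_pixels_dist(somata$y_um[s], somata$x_um[s],
                               plaques[[i]]$outline, nr, pixel_size_um), 1)
        k <- in_band[which.min(d)]  # which.min takes the lower id on ties
        n_around[k] <- n_around[k] + 1L
      }
    }
  }
  data.frame(plaque_id = vapply(plaques, `[[`, 1L, "id"),
             n_within = n_within, n_around = n_around,
             n_total = n_within + n_around)
}

point_to_pixels_dist <- function(y_um, x_um, pix, nr, pixel_size_um) {
  py <- (((pix - 1) %% nr)) * pixel_size_um
  px <- (((pix - 1) %/% nr)) * pixel_size_um
  sqrt(min((py - y_um)^2 + (px - x_um)^2))
}

#' Correlation between plaque diameter and neurite count
#'
#' The field observation this tests is that the number of dystrophic
#' neurites around a plaque grows with the plaque's diameter.
#'
#' @param diameters_um numeric vector of plaque equivalent diameters.
#' @param neurite_counts integer vector, same length.
#' @return list with \code{pearson_r}, \code{spearman_rho}, \code{n} and the
#'   two p-values. Zero-variance input yields NaN with a warning.
#' @export
diameter_neurite_relation <- function(diameters_um, neurite_counts) {
  n <- length(diameters_um)
  if (n < 3 || length(neurite_counts) != n)
    stop("need >= 3 plaques with matching diameter and count vectors")
  pe <- correlation(diameters_um, neurite_counts, method = "pearson")
  sp <- correlation(diameters_um, neurite_counts, method = "spearman")
  list(pearson_r = pe$value, pearson_p = pe$p_value,
       spearman_rho = sp$value, spearman_p = sp$p_value, n = n)
}
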