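#' Label connected components
#'
#' Connected-component labeling of a binary mask. 8-connectivity (the
#' package default for all object counting) is obtained by merging
#' 4-connected labels across diagonal adjacencies.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels (0 = background), labels contiguous
#'   from 1, numbered deterministically in column-major scan order of each
#'   component's first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  storage.mode(lab) <- "integer"
  nlab <- max(lab)
  if (connectivity == 8 && nlab > 1) {
    pairs <- rbind(diag_pairs(lab, 1L, 1L), diag_pairs(lab, 1L, -1L))
    if (nrow(pairs) > 0) {
      g <- igraph::make_empty_graph(n = nlab, directed = FALSE)
      g <- igraph::add_edges(g, t(pairs))
      comp <- igraph::components(g)$membership
      lab[lab > 0] <- comp[lab[lab > 0]]
    }
  }
  relabel_scan_order(lab)
}

# label pairs straddling a diagonal offset (dy, dx)
diag_pairs <- function(lab, dy, dx) {
  nr <- nrow(lab); nc <- ncol(lab)
  r1 <- max(1, 1 - dy):min(nr, nr - dy)
  c1 <- max(1, 1 - dx):min(nc, nc - dx)
  a <- lab[r1, c1, drop = FALSE]
  b <- lab[r1 + dy, c1 + dx, drop = FALSE]
  keep <- a > 0 & b > 0 & a != b
  unique(cbind(a[keep], b[keep]))
}

# renumber labels 1..k by first occurrence in column-major order
relabel_scan_order <- function(lab) {
  u <- unique(lab[lab > 0])
  if (length(u) == 0) return(lab)
  remap <- integer(max(u))
  remap[u] <- seq_along(u)
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

# per-label pixel counts and centroids (1-based pixel indices)
component_stats <- function(lab) {
  idx <- which(lab > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(), n_pixels = integer(),
                      cy = numeric(), cx = numeric()))
  l <- lab[idx]
  rows <- ((idx - 1) %% nrow(lab)) + 1
  cols <- ((idx - 1) %/% nrow(lab)) + 1
  n <- tabulate(l)
  data.frame(label = seq_along(n), n_pixels = n,
             cy = rowsum(rows, l)[, 1] / n, cx = rowsum(cols, l)[, 1] / n)
}
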