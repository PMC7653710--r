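#' Skeletonize a binary mask
#'
#' Morphological thinning to 1-pixel-wide curves by the two-subiteration
#' Zhang-Suen scheme, iterated to a fixed point (hence idempotent). The
#' skeleton is a subset of the mask and the number of 8-connected
#' components is preserved: a component the thinning would erase entirely
#' (this happens for tiny compact blobs such as an isolated 2x2 square) is
#' retained as its single most central pixel.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical matrix, the skeleton.
#' @export
skeletonize <- function(mask) {
  m <- mask != 0
  if (!any(m)) return(m)
  lab0 <- label_components(m, connectivity = 8)
  sk <- remove_2x2(zhang_suen(m))
  # restore components erased entirely
  gone <- setdiff(unique(lab0[lab0 > 0]), unique(lab0[sk]))
  for (l in gone) {
    pix <- which(lab0 == l)
    rows <- ((pix - 1) %% nrow(m)) + 1
    cols <- ((pix - 1) %/% nrow(m)) + 1
    k <- which.min((rows - mean(rows))^2 + (cols - mean(cols))^2)
    sk[pix[k]] <- TRUE
  }
  sk
}

# Zhang-Suen thinning, vectorised over the whole image.
zhang_suen <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- zs_neighbors(pad, nr, nc)
      B <- nb$P2 + nb$P3 + nb$P4 + nb$P5 + nb$P6 + nb$P7 + nb$P8 + nb$P9
      seqs <- list(nb$P2, nb$P3, nb$P4, nb$P5, nb$P6, nb$P7, nb$P8, nb$P9, nb$P2)
      A <- matrix(0L, nr, nc)
      for (i in 1:8) A <- A + (seqs[[i]] == 0L & seqs[[i + 1]] == 1L)
      if (sub == 1) {
        c1 <- nb$P2 * nb$P4 * nb$P6 == 0L
        c2 <- nb$P4 * nb$P6 * nb$P8 == 0L
      } else {
        c1 <- nb$P2 * nb$P4 * nb$P8 == 0L
        c2 <- nb$P2 * nb$P6 * nb$P8 == 0L
      }
      del <- pad[2:(nr + 1), 2:(nc + 1)] & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        pad[2:(nr + 1), 2:(nc + 1)][del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1), 2:(nc + 1)]
}

# Zhang-Suen can leave an occasional filled 2x2 block; delete one simple
# pixel per block (a pixel whose foreground 8-neighbourhood stays connected
# without it) until none remain, so downstream metrics see a 1-px skeleton.
remove_2x2 <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  if (nr < 2 || nc < 2) return(sk)
  repeat {
    blk <- which(sk[-nr, -nc] & sk[-1, -nc] & sk[-nr, -1] & sk[-1, -1])
    if (length(blk) == 0) return(sk)
    b <- blk[1]
    r <- ((b - 1) %% (nr - 1)) + 1
    c <- ((b - 1) %/% (nr - 1)) + 1
    cand <- rbind(c(r, c), c(r, c + 1), c(r + 1, c), c(r + 1, c + 1))
    removed <- FALSE
    for (i in 1:4) {
      if (is_simple_pixel(sk, cand[i, 1], cand[i, 2])) {
        sk[cand[i, 1], cand[i, 2]] <- FALSE
        removed <- TRUE
        break
      }
    }
    if (!removed) sk[cand[1, 1], cand[1, 2]] <- FALSE  # degenerate blob
  }
}

# TRUE if removing (r, c) leaves its foreground 8-neighbours in one
# 8-connected component (and it is not an isolated or end pixel)
is_simple_pixel <- function(sk, r, c) {
  nr <- nrow(sk); nc <- ncol(sk)
  win <- matrix(FALSE, 3, 3)
  rs <- (r - 1):(r + 1); cs <- (c - 1):(c + 1)
  ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
  win[ok_r, ok_c] <- sk[rs[ok_r], cs[ok_c]]
  win[2, 2] <- FALSE
  n_fg <- sum(win)
  if (n_fg < 2) return(FALSE)
  max(label_components(win, connectivity = 8)) == 1
}

# 8 neighbours in Zhang-Suen order (P2 = north, clockwise)
zs_neighbors <- function(pad, nr, nc) {
  sh <- function(dy, dx)
    matrix(as.integer(pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]), nr, nc)
  list(P2 = sh(-1, 0), P3 = sh(-1, 1), P4 = sh(0, 1), P5 = sh(1, 1),
       P6 = sh(1, 0), P7 = sh(1, -1), P8 = sh(0, -1), P9 = sh(-1, -1))
}

# 8-neighbour count of each skeleton pixel
neighbor_counts <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- as.integer(sk)
  acc <- matrix(0L, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    acc <- acc + pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  }
  acc
}

# degree in the reduced curve graph: orthogonal adjacencies plus diagonal
# adjacencies that are not corner shortcuts (a diagonal whose two pixels
# share an orthogonal skeleton neighbour runs across a corner of the digital
# curve, not along it). On a digital staircase every interior pixel then has
# degree 2, as on the underlying curve.
reduced_degree <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sk
  sh <- function(dy, dx) pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  deg <- sh(-1, 0) + sh(1, 0) + sh(0, -1) + sh(0, 1)
  for (dy in c(-1L, 1L)) for (dx in c(-1L, 1L)) {
    deg <- deg + (sh(dy, dx) & !sh(dy, 0L) & !sh(0L, dx))
  }
  matrix(as.integer(deg), nr, nc)
}

#' Skeleton morphometrics
#'
#' Process-endpoint count, branch-point count and total process length of a
#' 1-pixel-wide skeleton. All topology is read from the reduced curve
#' graph: pixels are nodes, edges are orthogonal adjacencies plus those
#' diagonal adjacencies that are not corner shortcuts (a diagonal whose two
#' pixels share an orthogonal skeleton neighbour crosses a corner of the
#' digital curve rather than following it — the skeleton-plugin
#' convention). An endpoint is a node of degree at most one; a branch pixel
#' has degree three or more, and adjacent branch pixels are merged into one
#' junction (so a T-crossing counts once). Length sums the graph's edges:
#' one pixel size per orthogonal step, sqrt(2) pixel sizes per diagonal
#' step. An isolated pixel is one endpoint with zero length.
#'
#' @param skeleton logical matrix, 1-px-wide (no filled 2x2 block).
#' @param pixel_size_um micrometres per pixel.
#' @return list with \code{n_endpoints}, \code{n_branch_points},
#'   \code{total_length_um}, \code{n_pixels}.
#' @export
skeleton_metrics <- function(skeleton, pixel_size_um = 1) {
  sk <- skeleton != 0
  thick <- if (nrow(sk) > 1 && ncol(sk) > 1)
    which(sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
          sk[-nrow(sk), -1] & sk[-1, -1]) else integer()
  if (length(thick) > 0) {
    r <- ((thick[1] - 1) %% (nrow(sk) - 1)) + 1
    c <- ((thick[1] - 1) %/% (nrow(sk) - 1)) + 1
    stop(sprintf("skeleton is not 1-px wide: filled 2x2 block at (%d, %d)", r, c))
  }
  if (!any(sk))
    return(list(n_endpoints = 0L, n_branch_points = 0L,
                total_length_um = 0, n_pixels = 0L))
  deg <- reduced_degree(sk)
  endpoints <- sk & deg <= 1
  branch_px <- sk & deg >= 3
  n_branch <- if (any(branch_px))
    max(label_components(branch_px, connectivity = 8)) else 0L
  len_px <- adjacent_pairs(sk, 0, 1) + adjacent_pairs(sk, 1, 0) +
    sqrt(2) * (diag_pairs_no_shortcut(sk, 1) + diag_pairs_no_shortcut(sk, -1))
  list(n_endpoints = sum(endpoints), n_branch_points = as.integer(n_branch),
       total_length_um = len_px * pixel_size_um, n_pixels = sum(sk))
}

# number of foreground pairs at offset (dy, dx); each pair counted once
adjacent_pairs <- function(sk, dy, dx) {
  nr <- nrow(sk); nc <- ncol(sk)
  r1 <- max(1, 1 - dy):min(nr, nr - dy)
  c1 <- max(1, 1 - dx):min(nc, nc - dx)
  sum(sk[r1, c1] & sk[r1 + dy, c1 + dx])
}

# diagonal pairs at offset (1, dx), excluding corner shortcuts: a diagonal
# whose two pixels share an orthogonal skeleton neighbour
diag_pairs_no_shortcut <- function(sk, dx) {
  nr <- nrow(sk); nc <- ncol(sk)
  if (nr < 2 || nc < 2) return(0L)
  r1 <- 1:(nr - 1)
  c1 <- max(1, 1 - dx):min(nc, nc - dx)
  a <- sk[r1, c1, drop = FALSE]                 # (r, c)
  b <- sk[r1 + 1, c1 + dx, drop = FALSE]        # (r+1, c+dx)
  v <- sk[r1 + 1, c1, drop = FALSE]             # shared vertical neighbour
  h <- sk[r1, c1 + dx, drop = FALSE]            # shared horizontal neighbour
  sum(a & b & !v & !h)
}

#' Prune short spur branches from a skeleton
#'
#' Repeatedly removes terminal branches (endpoint to junction paths) shorter
#' than \code{min_length_um}; thinning artefacts at soma crossings produce
#' such spurs. Branches ending at another endpoint (whole open curves) are
#' never removed.
#'
#' @param skeleton logical matrix.
#' @param pixel_size_um micrometres per pixel.
#' @param min_length_um branches strictly shorter than this are removed.
#' @return pruned skeleton (re-thinned so junction remnants stay 1-px wide).
#' @export
prune_skeleton <- function(skeleton, pixel_size_um = 1, min_length_um = 3) {
  sk <- skeleton != 0
  repeat {
    deg <- reduced_degree(sk)
    eps <- which(sk & deg <= 1)
    removed_any <- FALSE
    for (e in eps) {
      path <- trace_from_endpoint(sk, e, deg)
      if (path$hit_junction && path$length_px * pixel_size_um < min_length_um) {
        sk[path$pixels] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
    sk <- zhang_suen(sk)
  }
  sk
}

# walk from an endpoint along the reduced curve graph until a junction
# (reduced degree >= 3) or a dead end; returns the branch pixels (junction
# excluded) and the path length
trace_from_endpoint <- function(sk, start, deg = reduced_degree(sk)) {
  nr <- nrow(sk)
  nb_off <- c(-1, 1, -nr, nr, -nr - 1, -nr + 1, nr - 1, nr + 1)
  nbdiag <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  path <- start
  cur <- start
  len <- 0
  repeat {
    cand <- cur + nb_off
    r <- ((cur - 1) %% nr) + 1
    ok <- rep(TRUE, 8)
    if (r == 1) ok[c(1, 5, 7)] <- FALSE
    if (r == nr) ok[c(2, 6, 8)] <- FALSE
    keep <- ok & cand >= 1 & cand <= length(sk)
    cand_ok <- cand[keep]
    diag_ok <- nbdiag[keep]
    sel <- sk[cand_ok] & !(cand_ok %in% path)
    # reduced graph: drop corner-shortcut diagonals (shared orth neighbour)
    if (any(sel & diag_ok)) {
      for (j in which(sel & diag_ok)) {
        d <- cand_ok[j] - cur
        dy <- ((cand_ok[j] - 1) %% nr) - ((cur - 1) %% nr)
        dxs <- d - dy
        via1 <- cur + dy          # vertical step
        via2 <- cur + dxs         # horizontal step
        if ((via1 >= 1 && via1 <= length(sk) && sk[via1]) ||
            (via2 >= 1 && via2 <= length(sk) && sk[via2]))
          sel[j] <- FALSE
      }
    }
    nxt <- cand_ok[sel]
    dg <- diag_ok[sel]
    if (length(nxt) == 0)
      return(list(pixels = path, length_px = len, hit_junction = FALSE))
    nxt1 <- nxt[1]; dg1 <- dg[1]
    if (deg[nxt1] >= 3)
      return(list(pixels = path, length_px = len + ifelse(dg1, sqrt(2), 1),
                  hit_junction = TRUE))
    path <- c(path, nxt1)
    len <- len + ifelse(dg1, sqrt(2), 1)
    cur <- nxt1
    if (length(path) > length(sk)) stop("pruning walk did not terminate")
  }
}

#' Select per-cell skeletons
#'
#' Automated stand-in for the visual selection of skeletons representing a
#' single microglial cell: keep skeleton components whose total process
#' length lies in \code{[min_length_um, max_length_um]} and which overlap
#' exactly one soma; components overlapping two or more somata are rejected
#' and flagged as merged.
#'
#' @param skeleton logical matrix (whole-image skeleton).
#' @param soma_mask logical matrix of detected somata (or \code{NULL} to
#'   skip the soma criterion).
#' @param pixel_size_um micrometres per pixel.
#' @param min_length_um,max_length_um length acceptance window.
#' @param prune_um spur-pruning threshold applied per component before
#'   measuring (0 disables).
#' @return list with \code{cells}: list of per-cell skeleton masks with
#'   their \code{\link{skeleton_metrics}}, and \code{n_rejected_merged}.
#' @export
select_cells <- function(skeleton, soma_mask = NULL, pixel_size_um = 1,
                         min_length_um = 5, max_length_um = 1000,
                         prune_um = 3) {
  lab <- label_components(skeleton != 0, connectivity = 8)
  soma_lab <- if (!is.null(soma_mask))
    label_components(soma_mask != 0, connectivity = 8) else NULL
  cells <- list()
  n_merged <- 0L
  for (l in seq_len(max(lab, 0))) {
    comp <- lab == l
    if (!is.null(soma_lab)) {
      # somata whose component lies within 2 px of this skeleton component
      d <- EBImage::imageData(EBImage::distmap(!comp))
      near <- unique(soma_lab[soma_lab > 0 & d <= 2])
      if (length(near) >= 2) { n_merged <- n_merged + 1L; next }
      if (length(near) == 0) next
    }
    sk <- if (prune_um > 0) prune_skeleton(comp, pixel_size_um, prune_um) else comp
    met <- skeleton_metrics(sk, pixel_size_um)
    if (met$total_length_um < min_length_um ||
        met$total_length_um > max_length_um) next
    cells[[length(cells) + 1L]] <- c(list(mask = sk, cell_id = length(cells) + 1L),
                                     met)
  }
  list(cells = cells, n_rejected_merged = n_merged)
}
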