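#' Configuration for a synthetic fluorescence section
#'
#' Defines the statistical structure of a simulated multi-channel cortical
#' section: plaques with log-normally distributed diameters, per-plaque
#' dystrophic-neurite counts whose Poisson mean grows linearly with plaque
#' diameter, plaque-clustered microglia whose density is scaled by a
#' condition factor (modelling the diet/diabetes suppression of microglial
#' clustering; 1 = control), lysosomal puncta inside microglial somata,
#' additive Gaussian noise and a smooth background gradient. Distributional
#' forms (log-normal diameters, Poisson counts) are modelling choices of
#' this simulator, not observed laws.
#'
#' @param field_size_um numeric length-2, field height and width in um.
#' @param pixel_size_um um per pixel (isotropic in plane).
#' @param z_slices number of z slices (rendered by replication with
#'   per-slice intensity jitter; ground truth is defined on the projection).
#' @param z_spacing_um z spacing, um (metadata only).
#' @param plaque_density plaques per mm^2.
#' @param plaque_diameter_lognormal \code{c(meanlog, sdlog)} of diameter um.
#' @param diameter_min_um,diameter_max_um truncation bounds of the diameter
#'   distribution.
#' @param neurite_rate \code{c(alpha, beta)}: per-plaque neurite count is
#'   Poisson with mean \code{alpha + beta * diameter_um}.
#' @param microglia_per_plaque_mean Poisson mean of plaque-associated
#'   microglia per plaque (before the condition factor).
#' @param condition_factor multiplier on the plaque-associated microglia
#'   mean and the lysosomal puncta rate; 1 = control.
#' @param background_microglia_density microglia per mm^2 far from plaques.
#' @param lysosome_rate Poisson mean of lysosomal puncta per microglial soma
#'   (before the condition factor).
#' @param noise_sigma additive Gaussian noise SD, intensity units (0-255
#'   scale).
#' @param background_gradient_amp peak-to-peak amplitude of the smooth
#'   background gradient.
#' @param plaque_margin_um minimum outline-to-outline separation enforced
#'   between plaques (plaques in tissue are discrete objects; this also
#'   keeps rendered plaques from merging into one segmented component).
#' @param microglia_min_gap_um minimum gap between microglial soma edges.
#'   The default (4) keeps somata resolvable as separate objects while
#'   allowing realistic clustering; per-cell morphometry fixtures raise it
#'   (about 42) so whole cells, processes included, never touch and every
#'   skeleton component is a single cell.
#' @param band_width_um proximity-band width used when planting neurites
#'   and microglia (default 30).
#' @param forced_plaques optional data frame \code{(y_um, x_um,
#'   diameter_um)} of plaques to plant deterministically instead of drawing
#'   them.
#' @param seed RNG seed; identical config + seed gives bit-identical output.
#' @return object of class \code{section_config}.
#' @export
section_config <- function(field_size_um = c(400, 400), pixel_size_um = 1,
                           z_slices = 1, z_spacing_um = 1,
                           plaque_density = 40,
                           plaque_diameter_lognormal = c(meanlog = log(20), sdlog = 0.3),
                           diameter_min_um = 10.5, diameter_max_um = 50,
                           neurite_rate = c(alpha = 2, beta = 0.4),
                           microglia_per_plaque_mean = 8,
                           condition_factor = 1,
                           background_microglia_density = 20,
                           lysosome_rate = 3,
                           noise_sigma = 5, background_gradient_amp = 10,
                           plaque_margin_um = 10, band_width_um = 30,
                           microglia_min_gap_um = 4,
                           forced_plaques = NULL, seed = 1) {
  cfg <- list(field_size_um = field_size_um, pixel_size_um = pixel_size_um,
              z_slices = z_slices, z_spacing_um = z_spacing_um,
              plaque_density = plaque_density,
              plaque_diameter_lognormal = plaque_diameter_lognormal,
              diameter_min_um = diameter_min_um,
              diameter_max_um = diameter_max_um,
              neurite_rate = neurite_rate,
              microglia_per_plaque_mean = microglia_per_plaque_mean,
              condition_factor = condition_factor,
              background_microglia_density = background_microglia_density,
              lysosome_rate = lysosome_rate,
              noise_sigma = noise_sigma,
              background_gradient_amp = background_gradient_amp,
              plaque_margin_um = plaque_margin_um,
              band_width_um = band_width_um,
              microglia_min_gap_um = microglia_min_gap_um,
              forced_plaques = forced_plaques, seed = seed)
  validate_section_config(cfg)
  class(cfg) <- "section_config"
  cfg
}

validate_section_config <- function(cfg) {
  with(cfg, {
    if (length(field_size_um) != 2 || any(field_size_um <= 0))
      stop("field_size_um must be two positive numbers")
    stopifnot_scalar_pos(pixel_size_um, "pixel_size_um")
    if (z_slices < 1) stop("z_slices must be >= 1")
    for (nm in c("plaque_density", "microglia_per_plaque_mean",
                 "condition_factor", "background_microglia_density",
                 "lysosome_rate", "noise_sigma", "background_gradient_amp"))
      if (cfg[[nm]] < 0) stop("'", nm, "' must be >= 0")
    if (any(neurite_rate < 0)) stop("neurite_rate parameters must be >= 0")
    if (diameter_min_um >= diameter_max_um)
      stop("diameter_min_um must be < diameter_max_um")
    if (min(field_size_um) < 2 * diameter_max_um)
      stop("field smaller than twice the maximum plaque diameter: ",
           "annulus geometry undefined")
  })
  invisible(cfg)
}

#' Generate a synthetic multi-channel section with ground truth
#'
#' Renders a 4-channel section (plaque dye, microglial marker, lysosomal
#' marker, neurite marker) from a \code{\link{section_config}} and returns
#' it with complete ground truth: planted plaques, per-plaque neurite
#' counts and positions, microglia with their process topology, and the
#' noise-free binary masks per channel. Plaques are radially decaying
#' bright disks; microglia are a soma disk (8-12 um diameter) with 2-6
#' persistent-random-walk processes; lysosomal puncta lie only inside
#' somata; neurite puncta lie in the 0-30 um band of their plaque. Noise
#' and the background gradient are added last; ground truth is recorded
#' before noise.
#'
#' @param config a \code{section_config}.
#' @param render if \code{FALSE}, skip pixel rendering and return ground
#'   truth only (fast path for statistical simulations).
#' @return list with \code{stack} (an \code{\link{image_stack}} or
#'   \code{NULL}) and \code{gt} (ground truth; see details).
#' @export
generate_section <- function(config, render = TRUE) {
  validate_section_config(config)
  with_seed(config$seed, generate_section_impl(config, render))
}

generate_section_impl <- function(cfg, render) {
  px <- cfg$pixel_size_um
  ny <- round(cfg$field_size_um[1] / px)
  nx <- round(cfg$field_size_um[2] / px)
  area_mm2 <- prod(cfg$field_size_um) / 1e6
  band <- cfg$band_width_um

  ## --- plaques ----------------------------------------------------------
  if (!is.null(cfg$forced_plaques)) {
    pl <- cfg$forced_plaques
    plaques <- data.frame(id = seq_len(nrow(pl)), y_um = pl$y_um,
                          x_um = pl$x_um, diameter_um = pl$diameter_um)
  } else {
    n_pl <- stats::rpois(1, cfg$plaque_density * area_mm2)
    plaques <- place_plaques(n_pl, cfg)
  }
  n_pl <- nrow(plaques)

  ## --- neurites ---------------------------------------------------------
  lam <- cfg$neurite_rate[[1]] + cfg$neurite_rate[[2]] * plaques$diameter_um
  plaques$neurite_count <- if (n_pl) stats::rpois(n_pl, lam) else integer()
  neurites <- place_neurites(plaques, cfg)
  # drop planned puncta that could not be placed (field edge); keep GT honest
  if (n_pl) {
    placed <- tabulate(neurites$plaque_id, nbins = n_pl)
    plaques$neurite_count <- placed
  }

  ## --- microglia --------------------------------------------------------
  microglia <- place_microglia(plaques, cfg, ny, nx)

  ## --- lysosomal puncta -------------------------------------------------
  lyso <- place_lysosomes(microglia, cfg)

  gt <- list(plaques = plaques, neurites = neurites, microglia = microglia,
             lysosomes = lyso, condition_factor = cfg$condition_factor,
             config = cfg, masks = NULL)

  if (!render) return(list(stack = NULL, gt = gt))

  ## --- rendering --------------------------------------------------------
  ch <- render_channels(gt, ny, nx, px, cfg)
  gt$masks <- ch$masks
  data <- array(0, dim = c(ny, nx, cfg$z_slices, 4))
  grad <- background_gradient(ny, nx, cfg$background_gradient_amp)
  for (c4 in 1:4) {
    for (z in seq_len(cfg$z_slices)) {
      jit <- if (cfg$z_slices > 1) stats::runif(1, 0.9, 1) else 1
      sl <- ch$intensity[[c4]] * jit + grad
      if (cfg$noise_sigma > 0)
        sl <- sl + matrix(stats::rnorm(ny * nx, 0, cfg$noise_sigma), ny, nx)
      data[, , z, c4] <- pmin(pmax(sl, 0), 255)
    }
  }
  stack <- image_stack(data, px,
                       c("plaque", "microglia", "lysosome", "neurite"),
                       provenance = sprintf("synthetic seed=%d", cfg$seed))
  list(stack = stack, gt = gt)
}

# rejection-sample plaque centres: fully inside the field, pairwise
# outline separation >= plaque_margin_um
place_plaques <- function(n, cfg) {
  H <- cfg$field_size_um[1]; W <- cfg$field_size_um[2]
  ys <- xs <- ds <- numeric(0)
  for (i in seq_len(n)) {
    d <- rlnorm_trunc(cfg$plaque_diameter_lognormal,
                      cfg$diameter_min_um, cfg$diameter_max_um)
    r <- d / 2
    ok <- FALSE
    for (att in 1:200) {
      y <- stats::runif(1, r + 1, H - r - 1)
      x <- stats::runif(1, r + 1, W - r - 1)
      if (length(ys) == 0 ||
          all(sqrt((ys - y)^2 + (xs - x)^2) >= ds / 2 + r + cfg$plaque_margin_um)) {
        ok <- TRUE; break
      }
    }
    if (ok) { ys <- c(ys, y); xs <- c(xs, x); ds <- c(ds, d) }
  }
  data.frame(id = seq_along(ys), y_um = ys, x_um = xs, diameter_um = ds)
}

rlnorm_trunc <- function(par, lo, hi) {
  for (i in 1:1000) {
    d <- stats::rlnorm(1, par[[1]], par[[2]])
    if (d >= lo && d <= hi) return(d)
  }
  (lo + hi) / 2
}

# puncta area-uniform in the band outside each plaque outline, with a small
# inner/outer safety margin so rasterised distances stay inside the band,
# a minimum punctum separation so objects stay distinct, all inside field
place_neurites <- function(plaques, cfg, punct_sep_um = 9) {
  H <- cfg$field_size_um[1]; W <- cfg$field_size_um[2]
  out <- list()
  all_y <- numeric(0); all_x <- numeric(0)
  for (i in seq_len(nrow(plaques))) {
    R <- plaques$diameter_um[i] / 2
    r_lo <- R + 1.5; r_hi <- R + cfg$band_width_um - 1.5
    for (k in seq_len(plaques$neurite_count[i])) {
      for (att in 1:200) {
        rr <- sqrt(stats::runif(1, r_lo^2, r_hi^2))
        th <- stats::runif(1, 0, 2 * pi)
        y <- plaques$y_um[i] + rr * sin(th)
        x <- plaques$x_um[i] + rr * cos(th)
        if (y < 2 || y > H - 2 || x < 2 || x > W - 2) next
        if (length(all_y) && any(sqrt((all_y - y)^2 + (all_x - x)^2) < punct_sep_um)) next
        out[[length(out) + 1L]] <- c(plaques$id[i], y, x)
        all_y <- c(all_y, y); all_x <- c(all_x, x)
        break
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(plaque_id = integer(), y_um = numeric(), x_um = numeric()))
  m <- do.call(rbind, out)
  data.frame(plaque_id = as.integer(m[, 1]), y_um = m[, 2], x_um = m[, 3])
}

# plaque-associated microglia in (or just inside) the band, background
# microglia far from every plaque; processes as persistent random walks
# from the soma centre, recorded step by step for morphometry ground truth
place_microglia <- function(plaques, cfg, ny, nx) {
  H <- cfg$field_size_um[1]; W <- cfg$field_size_um[2]
  band <- cfg$band_width_um
  cells <- list()
  sy <- sx <- sr <- numeric(0)  # accepted soma centres/radii

  add_cell <- function(y, x, soma_r, plaque_id, location) {
    n_proc <- sample(2:6, 1)
    # evenly spread base angles with bounded jitter, plus a rejection step:
    # a cell whose processes run closer than 3 px of each other outside the
    # soma is redrawn, so every process stays a distinct resolvable branch
    for (attempt in 1:25) {
      base <- stats::runif(1, 0, 2 * pi) + (seq_len(n_proc) - 1) * 2 * pi / n_proc
      angles <- base + stats::runif(n_proc, -0.15, 0.15)
      paths <- vector("list", n_proc)
      total_len <- 0
      for (p in seq_len(n_proc)) {
        # walks start at the soma centre; length clears the soma by 8-16 um
        # so every process is visible outside the body
        len_um <- soma_r + stats::runif(1, 8, 16)
        n_steps <- round(len_um / cfg$pixel_size_um)
        th <- angles[p]
        py <- y; px_ <- x
        pts <- matrix(NA_real_, n_steps + 1, 2)
        pts[1, ] <- c(py, px_)
        steps_done <- 0
        for (s in seq_len(n_steps)) {
          th <- th + stats::rnorm(1, 0, 0.04)
          ny_ <- py + sin(th) * cfg$pixel_size_um
          nx_ <- px_ + cos(th) * cfg$pixel_size_um
          if (ny_ < 2 || ny_ > H - 2 || nx_ < 2 || nx_ > W - 2) break
          py <- ny_; px_ <- nx_
          steps_done <- s
          pts[s + 1, ] <- c(py, px_)
        }
        paths[[p]] <- pts[seq_len(steps_done + 1), , drop = FALSE]
        total_len <- total_len + steps_done * cfg$pixel_size_um
      }
      if (processes_separated(paths, y, x, soma_r + 1,
                              3 * cfg$pixel_size_um)) break
    }
    cells[[length(cells) + 1L]] <<- list(
      id = length(cells) + 1L, y_um = y, x_um = x, soma_radius_um = soma_r,
      plaque_id = plaque_id, location = location, n_processes = n_proc,
      endpoint_count = n_proc, total_process_length_um = total_len,
      paths = paths)
    sy <<- c(sy, y); sx <<- c(sx, x); sr <<- c(sr, soma_r)
  }

  sep_ok <- function(y, x, soma_r) {
    length(sy) == 0 ||
      all(sqrt((sy - y)^2 + (sx - x)^2) >=
            cfg$microglia_min_gap_um + soma_r + sr)
  }

  # plaque-associated
  for (i in seq_len(nrow(plaques))) {
    R <- plaques$diameter_um[i] / 2
    n_mg <- stats::rpois(1, cfg$microglia_per_plaque_mean * cfg$condition_factor)
    for (k in seq_len(n_mg)) {
      for (att in 1:300) {
        soma_r <- stats::runif(1, 4, 6)
        inside <- stats::runif(1) < 0.25 && R > soma_r + 2
        if (inside) {
          rr <- sqrt(stats::runif(1, 0, (R - soma_r - 1)^2))
        } else {
          d_out <- stats::runif(1, soma_r + 1, band - soma_r - 2)
          rr <- R + d_out
        }
        th <- stats::runif(1, 0, 2 * pi)
        y <- plaques$y_um[i] + rr * sin(th)
        x <- plaques$x_um[i] + rr * cos(th)
        # full cells only: processes reach at most soma_r + 16 um from the
        # centre, so this margin keeps every walk inside the field
        marg <- soma_r + 18
        if (y < marg || y > H - marg || x < marg || x > W - marg) next
        if (!sep_ok(y, x, soma_r)) next
        add_cell(y, x, soma_r, plaques$id[i],
                 if (inside) "plaque" else "band")
        break
      }
    }
  }

  # background, kept clear of every plaque band
  n_bg <- stats::rpois(1, cfg$background_microglia_density *
                          prod(cfg$field_size_um) / 1e6)
  for (k in seq_len(n_bg)) {
    for (att in 1:300) {
      soma_r <- stats::runif(1, 4, 6)
      y <- stats::runif(1, soma_r + 18, H - soma_r - 18)
      x <- stats::runif(1, soma_r + 18, W - soma_r - 18)
      if (nrow(plaques) > 0) {
        dc <- sqrt((plaques$y_um - y)^2 + (plaques$x_um - x)^2)
        if (any(dc < plaques$diameter_um / 2 + band + soma_r + 24)) next
      }
      if (!sep_ok(y, x, soma_r)) next
      add_cell(y, x, soma_r, NA_integer_, "background")
      break
    }
  }
  cells
}

# TRUE when, outside the soma, every pair of process walks keeps at least
# min_gap between any two of their points
processes_separated <- function(paths, cy, cx, soma_r, min_gap) {
  outs <- lapply(paths, function(p) {
    d <- sqrt((p[, 1] - cy)^2 + (p[, 2] - cx)^2)
    p[d > soma_r, , drop = FALSE]
  })
  n <- length(outs)
  if (n < 2) return(TRUE)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    pa <- outs[[a]]; pb <- outs[[b]]
    if (nrow(pa) == 0 || nrow(pb) == 0) next
    d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
    if (min(d2) < min_gap^2) return(FALSE)
  }
  TRUE
}

place_lysosomes <- function(microglia, cfg) {
  out <- list()
  for (cell in microglia) {
    n <- stats::rpois(1, cfg$lysosome_rate * cfg$condition_factor)
    if (n == 0) next
    rr <- sqrt(stats::runif(n, 0, (max(cell$soma_radius_um - 1.5, 0.5))^2))
    th <- stats::runif(n, 0, 2 * pi)
    out[[length(out) + 1L]] <- data.frame(
      microglia_id = cell$id,
      y_um = cell$y_um + rr * sin(th),
      x_um = cell$x_um + rr * cos(th))
  }
  if (length(out) == 0)
    return(data.frame(microglia_id = integer(), y_um = numeric(),
                      x_um = numeric()))
  do.call(rbind, out)
}

## ---- rasterisation ------------------------------------------------------

# pixel centre of pixel (i,j) sits at ((i-1)*px, (j-1)*px) um
um_to_px <- function(u, px) round(u / px) + 1

# rows/cols below are 0-based pixel coordinates; linear index is 1-based
disk_pixels <- function(ny, nx, y_um, x_um, r_um, px) {
  cy <- y_um / px; cx <- x_um / px; r <- r_um / px
  r0 <- max(0, floor(cy - r)); r1 <- min(ny - 1, ceiling(cy + r))
  c0 <- max(0, floor(cx - r)); c1 <- min(nx - 1, ceiling(cx + r))
  rows <- r0:r1; cols <- c0:c1
  dy <- rows - cy
  dx <- cols - cx
  inside <- outer(dy^2, dx^2, "+") <= r^2
  ij <- which(inside, arr.ind = TRUE)
  (cols[ij[, 2]] * ny) + rows[ij[, 1]] + 1
}

# radial plaque profile: plateau with a sharp logistic shoulder at radius R,
# calibrated so Otsu on the noise-free image recovers the planted diameter
# to about one pixel
plaque_profile_pixels <- function(ny, nx, y_um, x_um, R_um, px, amp = 200) {
  cy <- y_um / px; cx <- x_um / px; R <- R_um / px
  ext <- R + 3
  r0 <- max(0, floor(cy - ext)); r1 <- min(ny - 1, ceiling(cy + ext))
  c0 <- max(0, floor(cx - ext)); c1 <- min(nx - 1, ceiling(cx + ext))
  rows <- r0:r1; cols <- c0:c1
  d <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+"))
  val <- amp / (1 + exp((d - R) / 0.4))
  ij <- which(val > 0.5, arr.ind = TRUE)
  list(idx = (cols[ij[, 2]] * ny) + rows[ij[, 1]] + 1,
       val = val[val > 0.5])
}

render_channels <- function(gt, ny, nx, px, cfg) {
  amp <- c(plaque = 200, microglia = 180, lysosome = 180, neurite = 180)
  I <- replicate(4, matrix(0, ny, nx), simplify = FALSE)
  M <- replicate(4, matrix(FALSE, ny, nx), simplify = FALSE)

  for (i in seq_len(nrow(gt$plaques))) {
    pr <- plaque_profile_pixels(ny, nx, gt$plaques$y_um[i], gt$plaques$x_um[i],
                                gt$plaques$diameter_um[i] / 2, px, amp[["plaque"]])
    I[[1]][pr$idx] <- pmax(I[[1]][pr$idx], pr$val)
    M[[1]][disk_pixels(ny, nx, gt$plaques$y_um[i], gt$plaques$x_um[i],
                       gt$plaques$diameter_um[i] / 2, px)] <- TRUE
  }
  for (cell in gt$microglia) {
    M[[2]][disk_pixels(ny, nx, cell$y_um, cell$x_um, cell$soma_radius_um, px)] <- TRUE
    # processes render as the walk's own pixel chain: 1 px (~1 um) wide,
    # 8-connected because consecutive walk points are one pixel apart
    for (p in cell$paths) {
      rows0 <- pmin(pmax(round(p[, 1] / px), 0), ny - 1)
      cols0 <- pmin(pmax(round(p[, 2] / px), 0), nx - 1)
      M[[2]][cols0 * ny + rows0 + 1] <- TRUE
    }
  }
  if (nrow(gt$lysosomes) > 0)
    for (i in seq_len(nrow(gt$lysosomes)))
      M[[3]][disk_pixels(ny, nx, gt$lysosomes$y_um[i], gt$lysosomes$x_um[i],
                         1.2, px)] <- TRUE
  if (nrow(gt$neurites) > 0)
    for (i in seq_len(nrow(gt$neurites)))
      M[[4]][disk_pixels(ny, nx, gt$neurites$y_um[i], gt$neurites$x_um[i],
                         1.2, px)] <- TRUE
  for (c4 in 2:4) I[[c4]][M[[c4]]] <- amp[[c4]]
  names(I) <- names(M) <- c("plaque", "microglia", "lysosome", "neurite")
  list(intensity = I, masks = M)
}

background_gradient <- function(ny, nx, amp) {
  if (amp == 0) return(matrix(0, ny, nx))
  phi <- stats::runif(1, 0, 2 * pi)
  g <- outer(seq_len(ny) / ny * sin(phi), rep(1, nx)) +
       outer(rep(1, ny), seq_len(nx) / nx * cos(phi))
  rng <- range(g)
  if (diff(rng) == 0) return(matrix(amp / 2, ny, nx))
  amp * (g - rng[1]) / diff(rng)
}

#' Generate a two-group cohort of synthetic sections
#'
#' \code{n_per_group} sections per condition, each generated from a
#' distinct counter-derived sub-seed of the master seed, so any member is
#' reproducible in isolation.
#'
#' @param config_control,config_condition \code{section_config}s for the
#'   two groups (typically differing in \code{condition_factor}).
#' @param n_per_group sections per group (>= 1).
#' @param seed master seed.
#' @param render passed to \code{\link{generate_section}}.
#' @return list of \code{2 * n_per_group} elements, each with
#'   \code{stack}, \code{gt} and \code{group} ("control" / "condition").
#' @export
generate_cohort <- function(config_control, config_condition, n_per_group,
                            seed = 1, render = TRUE) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  out <- vector("list", 2 * n_per_group)
  k <- 0L
  for (grp in c("control", "condition")) {
    cfg <- if (grp == "control") config_control else config_condition
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(seed, k)
      sec <- generate_section(cfg_i, render = render)
      out[[k]] <- list(stack = sec$stack, gt = sec$gt, group = grp)
    }
  }
  out
}
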