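#' Write a section to a multi-channel TIFF
#'
#' One directory-entry per (z, channel) plane in fixed channel order
#' (plaque, microglia, lysosome, neurite, slowest index = channel); the
#' channel order, pixel size and z geometry are recorded in a JSON sidecar
#' file (\code{<path>.json}). Intensities (0-255 scale) are stored as
#' 8-bit.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_section_tiff <- function(stack, path) {
  d <- dim(stack$data)
  planes <- list()
  for (ch in seq_len(d[4])) for (z in seq_len(d[3]))
    planes[[length(planes) + 1L]] <- stack$data[, , z, ch] / 255
  jsonlite::write_json(list(channel_roles = stack$channel_roles,
                            pixel_size_um = stack$pixel_size_um,
                            z_slices = d[3]),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  tiff::writeTIFF(planes, path, bits.per.sample = 8)
  invisible(path)
}

#' Read a section TIFF written by \code{\link{write_section_tiff}}
#'
#' @param path TIFF path.
#' @param pixel_size_um,channel_roles overrides; when \code{NULL} they are
#'   taken from the JSON sidecar.
#' @return an \code{\link{image_stack}}.
#' @export
read_section_tiff <- function(path, pixel_size_um = NULL, channel_roles = NULL) {
  planes <- tiff::readTIFF(path, all = TRUE)
  nz <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    info <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) NULL)
    if (!is.null(info)) {
      if (is.null(pixel_size_um)) pixel_size_um <- info$pixel_size_um
      if (is.null(channel_roles)) channel_roles <- info$channel_roles
      nz <- info$z_slices
    }
  }
  if (is.null(pixel_size_um) || is.null(channel_roles))
    stop("malformed TIFF input: no sidecar metadata; supply pixel_size_um and channel_roles")
  nch <- length(channel_roles)
  if (is.null(nz)) nz <- length(planes) / nch
  ny <- nrow(planes[[1]]); nx <- ncol(planes[[1]])
  data <- array(0, c(ny, nx, nz, nch))
  k <- 0L
  for (ch in seq_len(nch)) for (z in seq_len(nz)) {
    k <- k + 1L
    data[, , z, ch] <- planes[[k]] * 255
  }
  image_stack(data, pixel_size_um, channel_roles, provenance = path)
}

#' Write ground truth as JSON plus per-object CSVs
#'
#' @param gt ground truth from \code{\link{generate_section}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(gt$plaques, file.path(dir, "plaques.csv"), row.names = FALSE)
  utils::write.csv(gt$neurites, file.path(dir, "neurites.csv"), row.names = FALSE)
  mg <- do.call(rbind, lapply(gt$microglia, function(m)
    data.frame(id = m$id, y_um = m$y_um, x_um = m$x_um,
               soma_radius_um = m$soma_radius_um,
               plaque_id = m$plaque_id, location = m$location,
               n_processes = m$n_processes,
               endpoint_count = m$endpoint_count,
               total_process_length_um = m$total_process_length_um)))
  if (is.null(mg)) mg <- data.frame()
  utils::write.csv(mg, file.path(dir, "microglia.csv"), row.names = FALSE)
  utils::write.csv(gt$lysosomes, file.path(dir, "lysosomes.csv"), row.names = FALSE)
  summary <- list(condition_factor = gt$condition_factor,
                  seed = gt$config$seed,
                  n_plaques = nrow(gt$plaques),
                  n_microglia = length(gt$microglia),
                  n_neurites = nrow(gt$neurites))
  jsonlite::write_json(summary, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read or write a section configuration as YAML
#'
#' Every \code{\link{section_config}} field is addressable by key.
#'
#' @param path YAML file path.
#' @return a \code{section_config}.
#' @export
read_section_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(section_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$forced_plaques))
    vals$forced_plaques <- as.data.frame(vals$forced_plaques)
  do.call(section_config, vals)
}

#' @rdname read_section_config
#' @param config a \code{section_config} to serialise.
#' @export
write_section_config <- function(config, path) {
  out <- unclass(config)
  if (!is.null(out$forced_plaques)) out$forced_plaques <- as.list(out$forced_plaques)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
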