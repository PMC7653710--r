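#' Quantify one section end to end
#'
#' Runs the full measurement chain on a 4-channel stack: segment each
#' channel, detect plaques (9.9 um diameter filter), build each plaque's
#' proximity band, quantify every marker inside the plaque and in the band,
#' detect microglial somata and count plaque-associated microglia.
#'
#' @param stack an \code{\link{image_stack}} with roles plaque, microglia,
#'   lysosome, neurite.
#' @param band_width_um proximity-band width (default 30).
#' @param min_diameter_um plaque diameter filter (default 9.9).
#' @param ball_radius_px,sigma_px preprocessing parameters (see
#'   \code{\link{segment_channel}}).
#' @param soma_min_area_um2 minimum soma area for counting.
#' @param markers which marker channels to quantify in the bands (subset of
#'   microglia, lysosome, neurite); restricting them skips the unneeded
#'   segmentations.
#' @param exclude_clipped drop border-clipped plaques from per-plaque
#'   statistics (default TRUE; they are still listed, flagged).
#' @return list: \code{plaques} (data frame), \code{plaque_objects},
#'   \code{bands}, \code{band_quant} (long data frame plaque x marker),
#'   \code{somata}, \code{microglia_counts}, \code{masks},
#'   \code{thresholds}, \code{params}.
#' @export
quantify_section <- function(stack, band_width_um = 30, min_diameter_um = 9.9,
                             ball_radius_px = 25, sigma_px = 2,
                             soma_min_area_um2 = 20,
                             markers = c("microglia", "lysosome", "neurite"),
                             exclude_clipped = TRUE) {
  px <- stack$pixel_size_um
  markers <- match.arg(markers, several.ok = TRUE)
  roles <- unique(c("plaque", "microglia", markers))
  seg <- lapply(roles, function(r)
    segment_channel(stack, r, ball_radius_px = ball_radius_px,
                    sigma_px = sigma_px))
  names(seg) <- roles
  plaques <- detect_plaques(seg$plaque$mask, px, min_diameter_um)
  pdf_ <- plaques_df(plaques)
  keep <- if (exclude_clipped && nrow(pdf_)) !pdf_$clipped else rep(TRUE, nrow(pdf_))
  plaques_kept <- plaques[keep]
  bands <- lapply(plaques_kept, band_mask, width_um = band_width_um)
  marker_labs <- lapply(stats::setNames(markers, markers), function(r)
    label_components(seg[[r]]$mask, connectivity = 8))
  bq <- list()
  for (i in seq_along(plaques_kept)) {
    for (r in markers) {
      q <- quantify_band(seg[[r]]$image, seg[[r]]$mask, plaques_kept[[i]],
                         bands[[i]], marker_labels = marker_labs[[r]])
      bq[[length(bq) + 1L]] <- data.frame(
        plaque_id = q$plaque_id, marker = r,
        area_in_plaque_um2 = q$area_in_plaque_um2,
        area_in_band_um2 = q$area_in_band_um2,
        mean_intensity_band = q$mean_intensity_band,
        n_objects_band = q$n_objects_band,
        band_area_um2 = q$band_area_um2,
        band_clipped = q$band_clipped)
    }
  }
  somata <- detect_somata(seg$microglia$mask, px, soma_min_area_um2)
  mg <- if (length(plaques_kept))
    count_plaque_microglia(somata, plaques_kept, bands, px)
  else data.frame(plaque_id = integer(), n_within = integer(),
                  n_around = integer(), n_total = integer())
  list(plaques = pdf_, plaque_objects = plaques_kept, bands = bands,
       band_quant = if (length(bq)) do.call(rbind, bq) else
         data.frame(plaque_id = integer(), marker = character(),
                    area_in_plaque_um2 = numeric(), area_in_band_um2 = numeric(),
                    mean_intensity_band = numeric(), n_objects_band = integer(),
                    band_area_um2 = numeric(), band_clipped = logical()),
       somata = somata, microglia_counts = mg,
       masks = lapply(seg, `[[`, "mask"),
       thresholds = lapply(seg, `[[`, "threshold"),
       params = list(band_width_um = band_width_um,
                     min_diameter_um = min_diameter_um,
                     ball_radius_px = ball_radius_px, sigma_px = sigma_px,
                     soma_min_area_um2 = soma_min_area_um2,
                     markers = markers,
                     exclude_clipped = exclude_clipped,
                     pixel_size_um = px))
}

#' Run the full study pipeline on a simulated cohort
#'
#' Simulate, segment and quantify a two-group cohort, then run the group
#' statistics: per-section summaries, pooled diameter-neurite correlation,
#' and the group comparison of plaque-associated microglia counts and
#' band-positive marker areas (Mann-Whitney on per-section means).
#'
#' @param config_control,config_condition \code{\link{section_config}}s.
#' @param n_per_group sections per group.
#' @param seed master seed.
#' @param ... passed to \code{\link{quantify_section}}.
#' @return a study report list: \code{sections} (per-section quantification
#'   summaries), \code{section_table} (data frame of per-section means),
#'   \code{diameter_neurite}, \code{group_tests}, \code{seed}.
#' @export
run_pipeline <- function(config_control, config_condition, n_per_group = 3,
                         seed = 1, ...) {
  cohort <- generate_cohort(config_control, config_condition, n_per_group,
                            seed = seed, render = TRUE)
  sections <- lapply(cohort, function(s) {
    q <- quantify_section(s$stack, ...)
    list(group = s$group, quant = q, gt = s$gt)
  })
  st <- do.call(rbind, lapply(seq_along(sections), function(i) {
    q <- sections[[i]]$quant
    nb <- q$band_quant
    mgl <- nb[nb$marker == "microglia", , drop = FALSE]
    neu <- nb[nb$marker == "neurite", , drop = FALSE]
    data.frame(section = i, group = sections[[i]]$group,
               n_plaques = nrow(q$plaques),
               mean_diameter_um = if (nrow(q$plaques)) mean(q$plaques$diameter_um) else NA,
               mean_mg_per_plaque = if (nrow(q$microglia_counts))
                 mean(q$microglia_counts$n_total) else NA,
               mean_mg_band_area_um2 = if (nrow(mgl)) mean(mgl$area_in_band_um2) else NA,
               mean_neurites_per_plaque = if (nrow(neu)) mean(neu$n_objects_band) else NA)
  }))
  d_all <- unlist(lapply(sections, function(s) {
    neu <- s$quant$band_quant
    s$quant$plaques$diameter_um[match(
      neu$plaque_id[neu$marker == "neurite"], s$quant$plaques$id)]
  }))
  n_all <- unlist(lapply(sections, function(s) {
    neu <- s$quant$band_quant
    neu$n_objects_band[neu$marker == "neurite"]
  }))
  dn <- if (length(d_all) >= 3) diameter_neurite_relation(d_all, n_all) else NULL
  gt_tests <- list()
  for (v in c("mean_mg_per_plaque", "mean_mg_band_area_um2")) {
    a <- st[[v]][st$group == "control"]
    b <- st[[v]][st$group == "condition"]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    gt_tests[[v]] <- if (length(a) && length(b)) mann_whitney(a, b) else NULL
  }
  list(sections = sections, section_table = st, diameter_neurite = dn,
       group_tests = gt_tests, seed = seed)
}

#' Replicated cohort experiment (power / type-I calibration)
#'
#' Repeats a two-group cohort comparison over many seeded replicates and
#' records the per-replicate p-value for the condition effect on the mean
#' plaque-associated microglia count (Mann-Whitney, two-sided). Each group
#' has \code{n_per_group} animals with \code{sections_per_unit} sections
#' each; sections of one animal are averaged first and the animal is the
#' statistical unit, mirroring the three-slices-per-mouse design.
#' \code{measure = "pipeline"} measures counts with the full segmentation
#' chain; \code{measure = "ground_truth"} uses the planted counts (fast
#' path for large calibration runs).
#'
#' @param config_control,config_condition \code{\link{section_config}}s.
#' @param n_per_group animals per group in each replicate.
#' @param replicates number of replicates (>= 1).
#' @param seed master seed; replicate r uses sub-seed counter r.
#' @param measure \code{"pipeline"} or \code{"ground_truth"}.
#' @param sections_per_unit sections per animal (default 3).
#' @param alpha significance level for the summary fraction.
#' @param ... passed to \code{\link{quantify_section}} when measuring via
#'   the pipeline.
#' @return list: \code{table} (replicate, p, group means),
#'   \code{fraction_significant}, \code{alpha}.
#' @export
run_cohort_experiment <- function(config_control, config_condition,
                                  n_per_group = 6, replicates = 100,
                                  seed = 1,
                                  measure = c("pipeline", "ground_truth"),
                                  sections_per_unit = 3,
                                  alpha = 0.05, ...) {
  measure <- match.arg(measure)
  if (replicates < 1) stop("replicates must be >= 1")
  if (sections_per_unit < 1) stop("sections_per_unit must be >= 1")
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    coh <- generate_cohort(config_control, config_condition,
                           n_per_group * sections_per_unit,
                           seed = derive_seed(seed, r),
                           render = (measure == "pipeline"))
    per_sec <- vapply(coh, function(s) {
      if (measure == "ground_truth") {
        assoc <- vapply(s$gt$microglia, function(m) !is.na(m$plaque_id), TRUE)
        np <- nrow(s$gt$plaques)
        if (np == 0) return(NA_real_)
        sum(assoc) / np
      } else {
        q <- quantify_section(s$stack, ...)
        if (nrow(q$microglia_counts) == 0) return(NA_real_)
        mean(q$microglia_counts$n_total)
      }
    }, 1)
    grp <- vapply(coh, `[[`, "", "group")
    unit <- rep(rep(seq_len(n_per_group), each = sections_per_unit), 2)
    per_unit <- tapply(per_sec, list(grp, unit),
                       function(v) mean(v[is.finite(v)]))
    a <- per_unit["control", ]; b <- per_unit["condition", ]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    p <- if (length(a) && length(b)) mann_whitney(a, b)$p_value else NA_real_
    rows[[r]] <- data.frame(replicate = r, p = p,
                            mean_control = mean(a), mean_condition = mean(b))
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       fraction_significant = mean(tab$p < alpha, na.rm = TRUE),
       alpha = alpha)
}
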