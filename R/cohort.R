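#' Body mass index
#'
#' \code{weight (kg) / [height (m)]^2}, rounded half-up to one decimal —
#' the convention that reproduces the printed biopsy-cohort table.
#'
#' @param weight_kg weight in kilograms (> 0).
#' @param height_cm height in centimetres (> 0).
#' @param digits decimals for the printed value (default 1); \code{NULL}
#'   returns the unrounded value.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_cm, digits = 1) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be positive")
  v <- weight_kg / (height_cm / 100)^2
  if (is.null(digits)) v else round_half_up(v, digits)
}

#' HOMA-IR insulin-resistance index
#'
#' Two published unit conventions exist and the choice changes the value, so
#' the variant is required explicitly: \code{"si"} uses glucose in mmol/L
#' (divisor 22.5), \code{"conventional"} uses glucose in mg/dL
#' (divisor 405); insulin is in uU/mL in both.
#'
#' @param glucose fasting glucose (mmol/L for "si", mg/dL for "conventional").
#' @param insulin fasting insulin, uU/mL.
#' @param variant \code{"si"} or \code{"conventional"}; no default.
#' @return HOMA-IR (dimensionless).
#' @export
homa_ir <- function(glucose, insulin, variant) {
  if (missing(variant)) stop("HOMA-IR variant must be given explicitly ('si' or 'conventional')")
  variant <- match.arg(variant, c("si", "conventional"))
  if (any(glucose <= 0) || any(insulin <= 0)) stop("inputs must be positive")
  glucose * insulin / if (variant == "si") 22.5 else 405
}

#' Assign a subject to a metabolic group
#'
#' Groups follow the biopsy-cohort design: normal-weight (BMI < 25, no
#' T2D), obese (BMI > 30, no T2D) and obese with T2D (BMI > 30 + T2D).
#' Subjects in the 25-30 BMI gap, or with T2D but BMI <= 30, do not fit any
#' group and are returned as \code{"unclassified"} with a warning.
#'
#' @param bmi numeric BMI values.
#' @param t2d logical T2D diagnosis flags.
#' @return character vector of group labels.
#' @export
assign_group <- function(bmi, t2d) {
  stopifnot(length(bmi) == length(t2d))
  g <- rep("unclassified", length(bmi))
  g[bmi < 25 & !t2d] <- "BMI<25"
  g[bmi > 30 & !t2d] <- "BMI>30"
  g[bmi > 30 & t2d] <- "BMI>30+T2D"
  if (any(g == "unclassified"))
    warning(sum(g == "unclassified"), " subject(s) fit no group (BMI 25-30, or T2D without BMI > 30)")
  g
}

#' Load the packaged biopsy-cohort table
#'
#' Per-subject demographics and clinical status of the idiopathic
#' normal-pressure hydrocephalus biopsy cohort, as printed: gender, age,
#' weight, height, printed BMI, printed HOMA-IR, T2D and hypertension flags,
#' amyloid status and APOE genotype. The printed average row of the obese
#' non-T2D group is known not to be exactly recomputable from its three
#' members; see the column \code{group} and the package vignette.
#'
#' @param path CSV path; default the packaged fixture.
#' @return data frame, one row per subject.
#' @export
load_cohort <- function(path = system.file("extdata", "inph_cohort.csv",
                                           package = "plaqband")) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$t2d <- as.logical(d$t2d)
  d$hypertension <- as.logical(d$hypertension)
  d
}

#' Group summary row
#'
#' Means of the members' values at the table's printed precision: BMI is
#' averaged over the computed (unrounded) per-subject values then rounded
#' to one decimal; HOMA-IR is averaged over the printed values and rounded
#' to one decimal; age, weight and height means are returned unrounded.
#'
#' @param subjects cohort data frame (columns \code{age}, \code{weight_kg},
#'   \code{height_cm}, \code{homa_ir}, \code{group}).
#' @param group group label to summarise.
#' @return list: \code{group}, \code{n}, \code{mean_age}, \code{mean_weight},
#'   \code{mean_height}, \code{mean_bmi}, \code{mean_homa_ir}.
#' @export
group_summary <- function(subjects, group) {
  g <- subjects[subjects$group == group, , drop = FALSE]
  if (nrow(g) == 0) stop("empty group: ", group)
  list(group = group, n = nrow(g),
       mean_age = mean(g$age),
       mean_weight = mean(g$weight_kg),
       mean_height = mean(g$height_cm),
       mean_bmi = round_half_up(mean(bmi(g$weight_kg, g$height_cm, digits = NULL)), 1),
       mean_homa_ir = round_half_up(mean(g$homa_ir), 1))
}
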