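# LFB optical-density quantification from RGB section photographs with
# background correction and section/location averaging.

#' Mean red-channel intensity over a ROI
#'
#' The red channel is the quantification channel for LFB staining: stronger
#' blue (myelin) staining absorbs more red light, lowering red intensity.
#'
#' @param rgb Numeric array `h x w x 3` with 8-bit values (0..255).
#' @param roi Logical matrix `h x w` selecting the ROI.
#' @return Mean red intensity (8-bit units, computed in float).
#' @export
red_channel_mean <- function(rgb, roi) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3,
            identical(dim(roi), dim(rgb)[1:2]))
  if (!any(roi)) stop("empty ROI")
  mean(rgb[, , 1][roi])
}

#' Background correction factor from off-tissue ROIs
#'
#' Mean of the red-channel means of the background ROIs placed outside the
#' tissue (conventionally four per photograph).
#'
#' @param rgb Numeric array `h x w x 3` (8-bit values).
#' @param rois List of logical ROI matrices.
#' @param tissue Optional logical tissue mask; a warning is issued for any
#'   background ROI overlapping it.
#' @return Background intensity `I_B` (8-bit units).
#' @export
background_factor <- function(rgb, rois, tissue = NULL) {
  stopifnot(length(rois) >= 1)
  if (!is.null(tissue))
    for (i in seq_along(rois))
      if (any(rois[[i]] & tissue))
        warning(sprintf("background ROI %d overlaps tissue", i))
  mean(vapply(rois, function(r) red_channel_mean(rgb, r), numeric(1)))
}

#' LFB optical density
#'
#' `OD = 100 * (1 - I_R / I_B)` (percent): higher values mean more myelin.
#' ROIs brighter than the background give negative OD and are flagged with
#' a message.
#'
#' @param I_R Mean ROI red intensity.
#' @param I_B Background correction factor (> 0).
#' @return Optical density (percent); vectorized.
#' @export
lfb_od <- function(I_R, I_B) {
  stopifnot(all(I_B > 0))
  od <- 100 * (1 - I_R / I_B)
  if (any(od < 0))
    message(sum(od < 0), " ROI(s) brighter than background (negative OD)")
  od
}

#' Quantify a set of rendered/photographed sections
#'
#' Applies [red_channel_mean()], [background_factor()] and [lfb_od()] to each
#' section and ROI, producing raw per-section measurements.
#'
#' @param sections List of RGB arrays (one per adjacent section).
#' @param rois Named list of logical ROI matrices (names = structure or ROI
#'   identifiers).
#' @param bg_rois List of background ROI matrices (outside tissue).
#' @param animal_id,group,location Metadata copied into the output rows.
#' @return Raw measurement data frame (columns `animal_id`, `group`,
#'   `structure`, `location`, `section_index`, `roi_index`, `measure`,
#'   `value`).
#' @export
quantify_lfb_sections <- function(sections, rois, bg_rois,
                                  animal_id = "a01", group = "control",
                                  location = 1L) {
  rows <- list()
  for (s in seq_along(sections)) {
    ib <- background_factor(sections[[s]], bg_rois)
    for (r in seq_along(rois)) {
      ir <- red_channel_mean(sections[[s]], rois[[r]])
      rows[[length(rows) + 1]] <- data.frame(
        animal_id = animal_id, group = group,
        structure = names(rois)[r] %||% as.character(r),
        location = location, section_index = s, roi_index = r,
        measure = "lfb_od_percent", value = lfb_od(ir, ib),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate raw ROI measurements into the analysis table
#'
#' Averages raw per-section, per-ROI values per animal, structure and
#' location (histology: over the adjacent sections and the structure's ROIs)
#' and optionally collapses locations to per-animal structure means, the
#' level at which group statistics and MRI-histology correlations are
#' computed.  Missing sections simply average over what is available (a
#' warning reports unbalanced section counts).
#'
#' @param raw Raw measurement data frame (see [quantify_lfb_sections()] /
#'   [simulate_cohort()]); must contain `animal_id`, `group`, `structure`,
#'   `location`, `measure`, `value`.
#' @param collapse `"location"` keeps per-location rows; `"structure"`
#'   additionally averages over locations.
#' @return Aggregated data frame with a `value` column of means.
#' @export
aggregate_measurements <- function(raw,
                                   collapse = c("location", "structure")) {
  collapse <- match.arg(collapse)
  need <- c("animal_id", "group", "structure", "location", "measure", "value")
  stopifnot(all(need %in% names(raw)))
  if ("section_index" %in% names(raw)) {
    ns <- stats::aggregate(section_index ~ animal_id + structure + location +
                             measure, data = raw,
                           FUN = function(x) length(unique(x)))
    hist_ns <- ns$section_index[ns$measure == "lfb_od_percent"]
    if (length(hist_ns) && length(unique(hist_ns)) > 1)
      warning("unbalanced section counts; averaging over available sections")
  }
  out <- stats::aggregate(value ~ animal_id + group + structure + location +
                            measure, data = raw, FUN = mean)
  if (collapse == "structure")   # mean of per-location means
    out <- stats::aggregate(value ~ animal_id + group + structure + measure,
                            data = out, FUN = mean)
  out[order(out$measure, out$group, out$animal_id, out$structure), ,
      drop = FALSE]
}
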