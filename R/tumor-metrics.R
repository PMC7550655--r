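#' Caliper tumor volume
#'
#' V = a^2 b / 2 with a the smaller diameter and b the diameter perpendicular
#' to it, both in mm — the standard ellipsoid approximation for caliper
#' measurements of subcutaneous xenografts. Swapped diameters are an error,
#' never silently reordered.
#'
#' @param d_short smaller diameter a, mm; 0 < a <= b. Vectorised.
#' @param d_long perpendicular diameter b, mm.
#' @return volume in mm^3.
#' @examples
#' tumorVolume(8, 10)   # 320 mm^3
#' @export
tumorVolume <- function(d_short, d_long) {
  if (any(!is.finite(d_short)) || any(!is.finite(d_long)))
    stop("d_short/d_long: must be finite")
  if (any(d_short <= 0)) stop("d_short: must be > 0")
  if (any(d_short > d_long))
    stop("d_short exceeds d_long: diameters appear swapped")
  d_short^2 * d_long * 0.5
}

#' Tumor inhibition rate
#'
#' Percent reduction of the treated group's mean tumor volume relative to the
#' untreated control: (V_control - V_treated) / V_control x 100. Negative
#' when the treated volume exceeds the control.
#'
#' @param v_control untreated mean volume, mm^3, > 0. Vectorised.
#' @param v_treated treated mean volume, mm^3.
#' @return inhibition rate in percent (unrounded; the reference tables print
#'   1 decimal place).
#' @examples
#' inhibitionRate(1039.8, 547.4)   # 47.4 at 1 d.p.
#' @export
inhibitionRate <- function(v_control, v_treated) {
  if (any(!is.finite(v_control)) || any(v_control <= 0))
    stop("v_control: must be finite and > 0")
  (v_control - v_treated) / v_control * 100
}

#' Mean and SD of a parameter map over a region of interest
#'
#' The ROI convention of the reference analysis is a 2D outline on the single
#' largest-cross-section slice, represented as a 3D mask nonzero on one
#' slice; whole-tumor 3D masks are accepted as a documented extension.
#'
#' @param map numeric array (any dimensionality).
#' @param mask logical/numeric array of the same shape; must select >= 1
#'   voxel, and the map must be finite there.
#' @return data.frame with columns mean, sd (n - 1 denominator; 0 for a
#'   single voxel) and n.
#' @export
roiSummary <- function(map, mask) {
  if (!identical(dim(map), dim(mask)))
    stop("mask: shape must match the map")
  v <- map[mask != 0]
  if (length(v) == 0L) stop("mask: selects no voxels")
  if (any(!is.finite(v))) stop("map: non-finite values inside the mask")
  data.frame(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
             n = length(v))
}

#' Group-by-timepoint summary cells of a longitudinal study table
#'
#' Computes mean, SD and n per quantity, group and time point from a
#' long-format study table, reproducing the layout of the reference study
#' tables. Cells with fewer than 2 records are reported absent, not an
#' error.
#'
#' @param records long-format data.frame with columns group, timepoint,
#'   quantity, value (as from [generateStudy()]).
#' @param groups,timepoints optional label orderings; default to order of
#'   first appearance.
#' @return data.frame with columns quantity, group, timepoint, mean, sd, n,
#'   ordered groups-within-quantity, timepoints within group.
#' @export
longitudinalSummary <- function(records, groups = unique(records$group),
                                timepoints = unique(records$timepoint)) {
  stopifnot(all(c("group", "timepoint", "quantity", "value") %in% names(records)))
  key <- interaction(records$quantity, records$group, records$timepoint,
                     drop = TRUE)
  cells <- lapply(split(records, key), function(d) {
    if (nrow(d) < 2L) return(NULL)
    data.frame(quantity = d$quantity[1L], group = d$group[1L],
               timepoint = d$timepoint[1L], mean = mean(d$value),
               sd = stats::sd(d$value), n = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cells)
  out <- out[order(match(out$quantity, unique(records$quantity)),
                   match(out$group, groups),
                   match(out$timepoint, timepoints)), ]
  rownames(out) <- NULL
  out
}

#' Format summary cells for display
#'
#' Renders a summary-cell table in the "mean +/- sd" layout of the reference
#' tables: one row per group, one column per time point.
#'
#' @param cells data.frame with columns quantity, group, timepoint, mean, sd.
#' @param quantity which quantity to render.
#' @param digits decimal places.
#' @return data.frame of formatted strings, groups as rows.
#' @export
formatSummaryTable <- function(cells, quantity, digits = 1) {
  cc <- cells[cells$quantity == quantity, ]
  if (nrow(cc) == 0L) stop("no cells for quantity ", quantity)
  tps <- unique(cc$timepoint); grs <- unique(cc$group)
  out <- data.frame(group = grs, stringsAsFactors = FALSE)
  for (tp in tps) {
    col <- vapply(grs, function(g) {
      r <- cc[cc$group == g & cc$timepoint == tp, ]
      if (nrow(r) == 0L) return(NA_character_)
      sprintf("%.*f ± %.*f", digits, r$mean, digits, r$sd)
    }, character(1))
    out[[tp]] <- col
  }
  out
}
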