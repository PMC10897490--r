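# Photoactivatable-GFP matrix-mixing assay: the GFP-positive area inside
# the mitochondrial mask is measured at each timepoint and normalized to
# the initially photoactivated area (t = 0), so a curve rising above 1
# reports spread of matrix content through fusion.

#' Measure a PA-GFP spread curve from one cell
#'
#' GFP-positive pixels are those inside the mitochondria mask whose
#' intensity exceeds a threshold fixed at t = 0 as `threshold_frac` times
#' the median intensity of the activated region (ROI intersected with the
#' mask). The positive area at each timepoint is normalized to t = 0.
#'
#' @param frames list of GFP intensity matrices, one per timepoint.
#' @param mask binary mitochondria mask (same dimensions).
#' @param roi photoactivation rectangle: list with rmin, rmax, cmin, cmax
#'   (1-based, inclusive).
#' @param timepoints_min numeric timepoints in minutes (default 0, 5, 10).
#' @param threshold_frac fraction of the ROI median activated intensity
#'   used as the positivity threshold (default 0.2).
#' @param cell_id optional identifier.
#' @return data.frame of class `fusion_curve`: cell_id, timepoint_min,
#'   area_px, normalized_area (first value exactly 1).
#' @export
measure_spread <- function(frames, mask, roi, timepoints_min = c(0, 5, 10),
                           threshold_frac = 0.2, cell_id = NA) {
  stopifnot(length(frames) == length(timepoints_min), length(frames) >= 1)
  if (!all(dim(frames[[1]]) == dim(mask))) stop("mask and frames differ in size")
  roi_mask <- matrix(FALSE, nrow(mask), ncol(mask))
  roi_mask[roi$rmin:roi$rmax, roi$cmin:roi$cmax] <- TRUE
  act <- roi_mask & mask > 0
  if (!any(act)) stop("photoactivation ROI does not overlap the mitochondria mask")
  med <- stats::median(frames[[1]][act])
  thr <- threshold_frac * med
  if (!is.finite(thr) || thr <= 0) stop("photoactivation failed: no signal in ROI at t = 0")
  area <- vapply(frames, function(fr) sum(fr > thr & mask > 0), numeric(1))
  if (area[1] == 0) stop("photoactivation failed: zero GFP-positive area at t = 0")
  structure(data.frame(cell_id = cell_id, timepoint_min = timepoints_min,
                       area_px = area, normalized_area = area / area[1]),
            class = c("fusion_curve", "data.frame"))
}

#' Average PA-GFP curves across cells
#'
#' Pointwise mean and SEM of normalized areas over cells; all curves must
#' share the same timepoint grid.
#'
#' @param curves list of `fusion_curve` data.frames from [measure_spread()].
#' @return data.frame: timepoint_min, mean_normalized_area, sem, n_cells.
#' @export
average_curves <- function(curves) {
  stopifnot(length(curves) >= 1)
  tp <- curves[[1]]$timepoint_min
  for (cv in curves) {
    if (!isTRUE(all.equal(cv$timepoint_min, tp))) {
      stop("curves have mismatched timepoint grids")
    }
  }
  mat <- vapply(curves, function(cv) cv$normalized_area, numeric(length(tp)))
  mat <- matrix(mat, nrow = length(tp))
  data.frame(timepoint_min = tp,
             mean_normalized_area = rowMeans(mat),
             sem = apply(mat, 1, .sem),
             n_cells = length(curves))
}
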