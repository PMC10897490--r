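# Segmentation of fluorescence images into labeled mitochondrial objects:
# background subtraction, thresholding, connected-component labeling, and
# per-object shape descriptors (area, perimeter, fitted-ellipse aspect ratio).

#' Segmentation parameters
#'
#' @param background_radius_px radius of the disc structuring element used
#'   for white top-hat background subtraction (default 50 px).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold intensity threshold, used only when
#'   `threshold_method = "fixed"`.
#' @param min_object_area_px objects smaller than this are discarded
#'   (default 4 px, suppressing single-pixel noise).
#' @param connectivity pixel connectivity for labeling, 4 or 8 (default 8,
#'   the particle-analysis convention).
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(background_radius_px = 50,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0.5,
                                min_object_area_px = 4, connectivity = 8) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(background_radius_px > 0, min_object_area_px >= 1,
            connectivity %in% c(4, 8))
  structure(list(background_radius_px = background_radius_px,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_object_area_px = as.integer(min_object_area_px),
                 connectivity = connectivity),
            class = "segmentation_params")
}

#' Background-subtract a fluorescence image
#'
#' Morphological white top-hat with a disc of radius
#' `background_radius_px`: removes any structure wider than the disc
#' (slowly varying background) while preserving mitochondria-scale objects.
#' Output is non-negative with the input's dimensions.
#'
#' @param image 2D numeric matrix.
#' @param params a [segmentation_params()].
#' @return background-subtracted matrix, `min >= 0`.
#' @export
preprocess_image <- function(image, params = segmentation_params()) {
  if (length(dim(image)) != 2) stop("image must be a 2D single-channel matrix")
  size <- 2L * ceiling(params$background_radius_px) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  out <- EBImage::whiteTopHat(EBImage::Image(image), brush)
  out <- as.matrix(EBImage::imageData(out))
  pmax(out, 0)
}

#' Threshold and label a preprocessed image
#'
#' Binarizes (Otsu by default), labels connected components, removes objects
#' below `min_object_area_px`, and returns labels contiguous from 1. An
#' all-background image yields an empty (all-zero) label map.
#'
#' @param image preprocessed 2D numeric matrix.
#' @param params a [segmentation_params()].
#' @return integer label matrix.
#' @export
segment_image <- function(image, params = segmentation_params()) {
  if (length(dim(image)) != 2) stop("image must be a 2D single-channel matrix")
  thr <- if (params$threshold_method == "otsu") {
    rng <- range(image)
    if (diff(rng) == 0) Inf else EBImage::otsu(EBImage::Image(image), range = rng)
  } else {
    params$fixed_threshold
  }
  bw <- image > thr
  if (!any(bw)) return(matrix(0L, nrow(image), ncol(image)))
  lab <- label_components(bw, params$connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= params$min_object_area_px)
  if (!length(keep)) return(matrix(0L, nrow(image), ncol(image)))
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

#' Per-object shape descriptors
#'
#' One row per labeled object: area, perimeter, centroid, and the
#' fitted-ellipse axes from second central moments. The aspect ratio is
#' major/minor axis length (>= 1), the particle-analysis convention for
#' mitochondrial AR; 1 for a circle, larger for elongated objects.
#'
#' @param labels integer label matrix (from [segment_image()]).
#' @param um_per_px optional calibration; adds an `area_um2` column.
#' @return data.frame with columns label, area_px, perimeter_px,
#'   centroid_row, centroid_col (1-based pixel coordinates), major_axis_px,
#'   minor_axis_px, aspect_ratio (and area_um2 when calibrated).
#' @export
shape_descriptors <- function(labels, um_per_px = NULL) {
  n <- max(labels)
  if (n == 0) {
    out <- data.frame(label = integer(0), area_px = numeric(0),
                      perimeter_px = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), major_axis_px = numeric(0),
                      minor_axis_px = numeric(0), aspect_ratio = numeric(0))
    if (!is.null(um_per_px)) out$area_um2 <- numeric(0)
    return(out)
  }
  mo <- EBImage::computeFeatures.moment(labels)
  sh <- EBImage::computeFeatures.shape(labels)
  major <- mo[, "m.majoraxis"]
  minor <- major * sqrt(pmax(0, 1 - mo[, "m.eccentricity"]^2))
  # a zero-thickness pixel row has no transverse moment; floor the minor
  # axis at one pixel so the ratio stays finite
  minor <- pmax(minor, 1)
  major <- pmax(major, minor)
  out <- data.frame(label = seq_len(n), area_px = sh[, "s.area"],
                    perimeter_px = sh[, "s.perimeter"],
                    centroid_row = mo[, "m.cx"], centroid_col = mo[, "m.cy"],
                    major_axis_px = major, minor_axis_px = minor,
                    aspect_ratio = major / minor)
  if (!is.null(um_per_px)) out$area_um2 <- out$area_px * um_per_px^2
  rownames(out) <- NULL
  out
}

#' Segment one cell image end to end
#'
#' Convenience wrapper: [preprocess_image()], [segment_image()],
#' [shape_descriptors()].
#'
#' @inheritParams preprocess_image
#' @inheritParams shape_descriptors
#' @return list with `labels` (integer matrix) and `objects` (data.frame).
#' @export
segment_cell <- function(image, params = segmentation_params(), um_per_px = NULL) {
  pre <- preprocess_image(image, params)
  labels <- segment_image(pre, params)
  list(labels = labels, objects = shape_descriptors(labels, um_per_px))
}
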