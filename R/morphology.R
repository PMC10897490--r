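# Per-cell aspect-ratio statistics and rule-based classification of
# mitochondrial network morphology into the four classical categories
# (Elongated, Fragmented, Hyperfused, Collapsed) plus an Intermediate
# fallback, with replicate-level condition summaries.

#' Classification parameters
#'
#' Explicit, reproducible operationalization of the classical by-eye
#' morphology categories.
#'
#' @param tubular_ar_min an object with aspect ratio at or above this is
#'   "tubular", below it "round" (default 2.0).
#' @param class_fraction fraction of objects that must be tubular (round)
#'   for the Elongated (Fragmented) call; strict `>` (default 0.9).
#' @param hyperfused_component_fraction minimum fraction of total
#'   mitochondrial area in the largest connected component (default 0.75).
#' @param hyperfused_circularity_max the largest component counts as
#'   tubular-dominated (reticular) when its circularity
#'   4*pi*area/perimeter^2 is at or below this (default 0.5; a disc has
#'   circularity ~1, a thin tube or network much less).
#' @param collapsed_radius_fraction clumping radius as a fraction of the
#'   cell image diagonal (default 0.15).
#' @param collapsed_area_fraction minimum fraction of mitochondrial area
#'   within the clumping radius of the area centroid (default 0.75).
#' @return object of class `classification_params`.
#' @export
classification_params <- function(tubular_ar_min = 2.0, class_fraction = 0.9,
                                  hyperfused_component_fraction = 0.75,
                                  hyperfused_circularity_max = 0.5,
                                  collapsed_radius_fraction = 0.15,
                                  collapsed_area_fraction = 0.75) {
  stopifnot(tubular_ar_min > 1,
            class_fraction > 0, class_fraction <= 1,
            hyperfused_component_fraction > 0, hyperfused_component_fraction <= 1,
            collapsed_radius_fraction > 0, collapsed_radius_fraction <= 1,
            collapsed_area_fraction > 0, collapsed_area_fraction <= 1)
  structure(list(tubular_ar_min = tubular_ar_min,
                 class_fraction = class_fraction,
                 hyperfused_component_fraction = hyperfused_component_fraction,
                 hyperfused_circularity_max = hyperfused_circularity_max,
                 collapsed_radius_fraction = collapsed_radius_fraction,
                 collapsed_area_fraction = collapsed_area_fraction),
            class = "classification_params")
}

#' Mean aspect ratio of a cell
#'
#' Unweighted arithmetic mean of per-object aspect ratios, the per-cell AR
#' statistic reported alongside the morphology classes.
#'
#' @param objects data.frame from [shape_descriptors()] with an
#'   `aspect_ratio` column.
#' @return numeric scalar.
#' @export
cell_mean_ar <- function(objects) {
  if (is.null(objects) || nrow(objects) == 0) {
    stop("cell has no segmented objects; mean AR is undefined")
  }
  mean(objects$aspect_ratio)
}

#' Classify one cell's mitochondrial network morphology
#'
#' Applies the explicit decision rules in priority order
#' Collapsed, Hyperfused, Elongated, Fragmented, Intermediate:
#' \itemize{
#'   \item Collapsed: fraction of mitochondrial area within
#'     `collapsed_radius_fraction` of the image diagonal around the
#'     mitochondrial area centroid is at least `collapsed_area_fraction`;
#'   \item Hyperfused: the largest connected component holds at least
#'     `hyperfused_component_fraction` of total area and is reticular
#'     (circularity at most `hyperfused_circularity_max`);
#'   \item Elongated: more than `class_fraction` of objects are tubular
#'     (AR >= `tubular_ar_min`);
#'   \item Fragmented: more than `class_fraction` of objects are round.
#' }
#'
#' @param objects data.frame from [shape_descriptors()].
#' @param labels the cell's integer label matrix.
#' @param params a [classification_params()].
#' @param cell_id optional identifier carried into the result.
#' @return one-row data.frame: cell_id, class, tubular_fraction,
#'   largest_component_fraction, clumping_index, mean_ar, n_objects.
#' @export
classify_cell <- function(objects, labels, params = classification_params(),
                          cell_id = NA) {
  if (is.null(objects) || nrow(objects) == 0 || max(labels) == 0) {
    stop("cannot classify an empty cell (no segmented mitochondria)")
  }
  tubular <- objects$aspect_ratio >= params$tubular_ar_min
  tubular_fraction <- mean(tubular)
  areas <- objects$area_px
  total <- sum(areas)
  i_max <- which.max(areas)
  largest_component_fraction <- areas[i_max] / total

  idx <- which(labels > 0L)
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  ctr <- c(mean(rr), mean(cc))
  radius <- params$collapsed_radius_fraction *
    sqrt(nrow(labels)^2 + ncol(labels)^2)
  clumping_index <- mean((rr - ctr[1])^2 + (cc - ctr[2])^2 <= radius^2)

  circ_max <- 4 * pi * objects$area_px[i_max] /
    max(objects$perimeter_px[i_max], 1)^2

  cls <- if (clumping_index >= params$collapsed_area_fraction) {
    "Collapsed"
  } else if (largest_component_fraction >= params$hyperfused_component_fraction &&
             circ_max <= params$hyperfused_circularity_max) {
    "Hyperfused"
  } else if (tubular_fraction > params$class_fraction) {
    "Elongated"
  } else if (1 - tubular_fraction > params$class_fraction) {
    "Fragmented"
  } else {
    "Intermediate"
  }
  data.frame(cell_id = cell_id, class = cls,
             tubular_fraction = tubular_fraction,
             largest_component_fraction = largest_component_fraction,
             clumping_index = clumping_index,
             mean_ar = cell_mean_ar(objects), n_objects = nrow(objects))
}

#' Morphology classes recognised by the classifier
#' @export
morphology_classes <- function() {
  c("Elongated", "Fragmented", "Hyperfused", "Collapsed", "Intermediate")
}

#' Summarize morphology classes per condition with SEM across replicates
#'
#' Converts per-cell class calls into, for each condition and class, the
#' mean percentage of cells across replicates and its standard error (the
#' replicate is the unit of error, as in triplicate experiments).
#'
#' @param cells data.frame with columns `condition`, `replicate`, `class`.
#' @return data.frame: condition, class, mean_pct, sem_pct, n_replicates.
#'   Per condition and replicate the percentages sum to 100.
#' @export
summarize_classes <- function(cells) {
  stopifnot(all(c("condition", "replicate", "class") %in% names(cells)))
  classes <- morphology_classes()
  out <- list()
  for (cond in unique(cells$condition)) {
    sub <- cells[cells$condition == cond, ]
    if (nrow(sub) == 0) stop("condition without cells: ", cond)
    reps <- unique(sub$replicate)
    pct <- vapply(reps, function(rp) {
      cl <- sub$class[sub$replicate == rp]
      if (!length(cl)) stop("replicate without cells: ", cond, "/", rp)
      100 * vapply(classes, function(k) mean(cl == k), numeric(1))
    }, numeric(length(classes)))
    pct <- matrix(pct, nrow = length(classes))
    out[[length(out) + 1]] <- data.frame(
      condition = cond, class = classes,
      mean_pct = rowMeans(pct),
      sem_pct = apply(pct, 1, .sem),
      n_replicates = length(reps))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-way ANOVA on per-cell mean aspect ratios
#'
#' Thin wrapper over [stats::aov()] comparing mean AR between conditions,
#' the standard test reported with AR analyses.
#'
#' @param cell_stats data.frame with columns `condition` and `mean_ar`.
#' @return list with `p_value`, the fitted `aov` object, and per-condition
#'   mean/SEM.
#' @export
ar_anova <- function(cell_stats) {
  stopifnot(all(c("condition", "mean_ar") %in% names(cell_stats)))
  if (length(unique(cell_stats$condition)) < 2) {
    stop("need at least two conditions for ANOVA")
  }
  fit <- stats::aov(mean_ar ~ condition, data = cell_stats)
  p <- summary(fit)[[1]][["Pr(>F)"]][1]
  by_cond <- do.call(rbind, lapply(split(cell_stats$mean_ar, cell_stats$condition),
                                   function(x) data.frame(mean_ar = mean(x),
                                                          sem = .sem(x),
                                                          n = length(x))))
  by_cond$condition <- rownames(by_cond)
  rownames(by_cond) <- NULL
  list(p_value = p, fit = fit, summary = by_cond)
}
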