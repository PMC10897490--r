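# Shared infrastructure: TIFF stack reading/writing with normalized axes,
# CSV tables stamped with the configuration hash, and YAML configuration.

#' Read a TIFF image or stack with normalized axes
#'
#' Axes are normalized to (t, channel, row, col): a single plane becomes a
#' (1, 1, H, W) array, a multi-page single-channel stack (T, 1, H, W), and
#' pages carrying C samples per pixel (T, C, H, W).
#'
#' @param path TIFF file.
#' @return 4D numeric array with dimensions (t, channel, row, col).
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF, file not found: ", path)
  # non-color multi-sample pages make libtiff warn about ExtraSamples
  pages <- tryCatch(suppressWarnings(tiff::readTIFF(path, all = TRUE)),
                    error = function(e) stop("cannot read TIFF ", path, ": ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  d1 <- dim(pages[[1]])
  H <- d1[1]; W <- d1[2]
  C <- if (length(d1) == 3) d1[3] else 1L
  out <- array(0, dim = c(length(pages), C, H, W))
  for (t in seq_along(pages)) {
    p <- pages[[t]]
    if (length(dim(p)) == 2) {
      out[t, 1, , ] <- p
    } else {
      for (ch in seq_len(C)) out[t, ch, , ] <- p[, , ch]
    }
  }
  out
}

#' Write a matrix, list of matrices, or (t, c, h, w) array as TIFF
#'
#' Values are stored as 32-bit float; intensities are expected in \[0, 1\].
#'
#' @param x matrix, list of matrices, or 4D array from [read_stack()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_stack <- function(x, path) {
  pages <- if (is.matrix(x)) {
    list(x)
  } else if (is.list(x)) {
    x
  } else if (length(dim(x)) == 4) {
    # one page per timepoint; channels become samples within the page
    lapply(seq_len(dim(x)[1]), function(t) {
      if (dim(x)[2] == 1) {
        x[t, 1, , ]
      } else {
        aperm(x[t, , , , drop = FALSE][1, , , ], c(2, 3, 1))
      }
    })
  } else {
    stop("unsupported image container")
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  pages <- lapply(pages, function(p) { p[p < 0] <- 0; p[p > 1] <- 1; p })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

# ---- CSV with config-hash stamp --------------------------------------------

.write_csv <- function(df, path, config_hash = NULL) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash)) writeLines(paste0("# config_hash: ", config_hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# ---- configuration ----------------------------------------------------------

#' Default pipeline configuration
#'
#' One nested list holding the calibration and every module's parameter
#' block, serializable to YAML and hashable for provenance stamping.
#'
#' @param seed global seed; per-stage streams are derived from it.
#' @return named list of class `mitoquant_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    calibration = list(um_per_px = 0.1, nm_per_unit = 1),
    segmentation = list(background_radius_px = 50, threshold_method = "otsu",
                        fixed_threshold = 0.5, min_object_area_px = 4,
                        connectivity = 8),
    classification = list(tubular_ar_min = 2.0, class_fraction = 0.9,
                          hyperfused_component_fraction = 0.75,
                          hyperfused_circularity_max = 0.5,
                          collapsed_radius_fraction = 0.15,
                          collapsed_area_fraction = 0.75),
    tracking = list(spot_sigma_px = 1.5, spot_threshold = 0.3, max_link_px = 5,
                    max_gap_frames = 1, dt_s = 3, min_event_s = 15,
                    adjacency_radius_px = 3, fusion_confirm_frames = 2),
    contacts = list(step_nm = 5, max_gap_nm = 60, gap_stat = "mean"),
    fusion = list(threshold_frac = 0.2, timepoints_min = c(0, 5, 10)),
    simulate = list(
      cells = list(n_per_class = 2, image_size_px = c(320, 320),
                   n_tubules = 16, n_blobs = 16),
      timelapse = list(n_frames = 60, n_events = 4,
                       dwell = list(name = "point", value = 30), p_fusion = 0.5),
      em = list(n_mito = 3,
                standoffs_nm = c(10, 25, 45, 80), arc_lengths_nm = c(300, 250, 200, 250)),
      pagfp = list(component_areas_px = c(600, 400, 300), roi_fraction = 0.2,
                   spread_fractions = c(0.2, 0.5, 0.8)))
  ), class = "mitoquant_config")
}

#' Read a YAML configuration, filling unset fields with defaults
#' @param path YAML file.
#' @return `mitoquant_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  merge <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  structure(merge(unclass(cfg), user), class = "mitoquant_config")
}

#' Hash a configuration for provenance stamping
#'
#' MD5 of the canonical YAML serialization; every CSV the pipeline writes
#' carries this hash so outputs are traceable to their configuration.
#'
#' @param config a `mitoquant_config`.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(config)), tf)
  unname(tools::md5sum(tf))
}
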