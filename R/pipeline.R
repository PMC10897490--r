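# Reproducible pipeline runner: binds the synthetic generators and the
# analysis stages into a stage list driven by one configuration, writing
# CSV tables stamped with the config hash plus a JSON run manifest.
# Rerunning with an identical config and seed reproduces identical files.

.seg_params_from <- function(cfg) {
  do.call(segmentation_params, cfg$segmentation)
}
.cls_params_from <- function(cfg) {
  do.call(classification_params, cfg$classification)
}
.trk_params_from <- function(cfg) {
  do.call(tracking_params, cfg$tracking)
}

.pipeline_stages <- c("simulate", "segment", "classify", "tether",
                      "contacts", "fusion")

#' Run the quantification pipeline
#'
#' Executes the requested stages in order against `out_dir`:
#' \describe{
#'   \item{simulate}{generate morphology images (one set per class), a
#'     tethering time-lapse, a traced EM scene and a PA-GFP series, with
#'     ground-truth tables, under per-stage seeds derived from the global
#'     seed.}
#'   \item{segment}{segment every simulated cell image to `objects.csv`
#'     and per-cell label TIFFs.}
#'   \item{classify}{classify every cell and summarize classes to
#'     `classes.csv` / `class_summary.csv`.}
#'   \item{tether}{track the time-lapse to `events.csv` /
#'     `tether_summary.csv`.}
#'   \item{contacts}{analyze the EM scene to `contacts.csv` /
#'     `contact_summary.csv`.}
#'   \item{fusion}{measure the PA-GFP series to `fusion_curves.csv`.}
#' }
#' Every CSV carries the configuration hash; `manifest.json` records the
#' hash, seed, package version, stages and per-file MD5 checksums.
#'
#' @param config a `mitoquant_config` (see [default_config()]).
#' @param stages character vector of stage names, run in the given order.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "segment", "classify"),
                         out_dir) {
  unknown <- setdiff(stages, .pipeline_stages)
  if (length(unknown)) {
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "),
         " (known: ", paste(.pipeline_stages, collapse = ", "), ")")
  }
  if (("contacts" %in% stages) && is.null(config$calibration$nm_per_unit)) {
    stop("contacts stage requires calibration$nm_per_unit in the config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  written <- character(0)
  note <- function(p) written <<- c(written, p)

  for (stage in stages) {
    res <- tryCatch(switch(stage,
      simulate = .stage_simulate(config, out_dir, hash, seed, note),
      segment = .stage_segment(config, out_dir, hash, note),
      classify = .stage_classify(config, out_dir, hash, note),
      tether = .stage_tether(config, out_dir, hash, note),
      contacts = .stage_contacts(config, out_dir, hash, note),
      fusion = .stage_fusion(config, out_dir, hash, note)),
      error = function(e) stop("stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
  }

  manifest <- list(
    config_hash = hash, seed = seed,
    package = "mitoquant",
    version = as.character(utils::packageVersion("mitoquant")),
    stages = stages,
    files = lapply(stats::setNames(nm = sort(unique(written))), function(p) {
      unname(tools::md5sum(file.path(out_dir, p)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.stage_simulate <- function(cfg, out_dir, hash, seed, note) {
  sc <- cfg$simulate
  # morphology cells, one batch per network class
  class_specs <- list(
    Elongated = list(n_tubules = sc$cells$n_tubules, n_blobs = 0),
    Fragmented = list(n_tubules = 0, n_blobs = sc$cells$n_blobs),
    Hyperfused = list(n_tubules = sc$cells$n_tubules, n_blobs = 0,
                      hyperfused = TRUE),
    Collapsed = list(n_tubules = 0, n_blobs = sc$cells$n_blobs,
                     collapsed = TRUE))
  truth <- list()
  k <- 0L
  for (cls in names(class_specs)) {
    for (i in seq_len(sc$cells$n_per_class)) {
      k <- k + 1L
      args <- c(class_specs[[cls]],
                list(image_size_px = sc$cells$image_size_px,
                     seed = .derive_seed(seed, paste0("cells", k))))
      sim <- gen_morphology_image(do.call(morphology_spec, args))
      id <- sprintf("cell_%03d", k)
      write_stack(sim$image, file.path(out_dir, paste0(id, ".tif")))
      note(paste0(id, ".tif"))
      truth[[k]] <- data.frame(cell_id = id, true_class = sim$class,
                               n_objects = nrow(sim$objects))
    }
  }
  .write_csv(do.call(rbind, truth), file.path(out_dir, "cells_truth.csv"), hash)
  note("cells_truth.csv")

  tl <- gen_timelapse(timelapse_spec(
    n_frames = sc$timelapse$n_frames, n_events = sc$timelapse$n_events,
    dwell_dist = sc$timelapse$dwell, p_fusion = sc$timelapse$p_fusion,
    dt_s = cfg$tracking$dt_s, seed = .derive_seed(seed, "timelapse")))
  stack <- array(0, dim = c(length(tl$foci), 2, nrow(tl$foci[[1]]),
                            ncol(tl$foci[[1]])))
  for (t in seq_along(tl$foci)) {
    stack[t, 1, , ] <- tl$foci[[t]]; stack[t, 2, , ] <- tl$mito[[t]]
  }
  write_stack(stack, file.path(out_dir, "timelapse.tif")); note("timelapse.tif")
  .write_csv(tl$truth, file.path(out_dir, "timelapse_truth.csv"), hash)
  note("timelapse_truth.csv")

  ner <- length(sc$em$standoffs_nm)
  em <- gen_em_scene(em_scene_spec(
    n_mito = sc$em$n_mito,
    er_segments = data.frame(
      target = rep_len(seq_len(sc$em$n_mito), ner),
      standoff_nm = sc$em$standoffs_nm, arc_length_nm = sc$em$arc_lengths_nm),
    nm_per_unit = cfg$calibration$nm_per_unit,
    seed = .derive_seed(seed, "em")))
  .write_csv(em$scene, file.path(out_dir, "em_scene.csv"), hash)
  .write_csv(em$truth_contacts, file.path(out_dir, "em_truth.csv"), hash)
  note("em_scene.csv"); note("em_truth.csv")

  pa <- gen_pagfp_series(pagfp_spec(
    component_areas_px = sc$pagfp$component_areas_px,
    roi_fraction = sc$pagfp$roi_fraction,
    timepoints_min = cfg$fusion$timepoints_min,
    spread_fractions = sc$pagfp$spread_fractions,
    seed = .derive_seed(seed, "pagfp")))
  write_stack(pa$frames, file.path(out_dir, "pagfp.tif")); note("pagfp.tif")
  write_stack(pa$mask, file.path(out_dir, "pagfp_mask.tif")); note("pagfp_mask.tif")
  jsonlite::write_json(pa$roi, file.path(out_dir, "pagfp_roi.json"),
                       auto_unbox = TRUE)
  note("pagfp_roi.json")
  .write_csv(pa$truth, file.path(out_dir, "pagfp_truth.csv"), hash)
  note("pagfp_truth.csv")
  invisible(NULL)
}

.stage_segment <- function(cfg, out_dir, hash, note) {
  sp <- .seg_params_from(cfg)
  tifs <- sort(list.files(out_dir, pattern = "^cell_\\d+\\.tif$"))
  if (!length(tifs)) stop("no cell images found; run the simulate stage first")
  rows <- list()
  for (f in tifs) {
    img <- read_stack(file.path(out_dir, f))[1, 1, , ]
    seg <- segment_cell(img, sp, um_per_px = cfg$calibration$um_per_px)
    id <- sub("\\.tif$", "", f)
    write_stack(seg$labels / 65535, file.path(out_dir, paste0(id, "_labels.tif")))
    note(paste0(id, "_labels.tif"))
    if (nrow(seg$objects)) {
      rows[[length(rows) + 1]] <- cbind(cell_id = id, seg$objects)
    }
  }
  obj <- do.call(rbind, rows)
  .write_csv(obj[, c("cell_id", "label", "area_px", "perimeter_px",
                     "aspect_ratio", "centroid_row", "centroid_col")],
             file.path(out_dir, "objects.csv"), hash)
  note("objects.csv")
  invisible(NULL)
}

.stage_classify <- function(cfg, out_dir, hash, note) {
  cp <- .cls_params_from(cfg)
  obj <- .read_csv(file.path(out_dir, "objects.csv"))
  rows <- list()
  for (id in unique(obj$cell_id)) {
    lab <- read_stack(file.path(out_dir, paste0(id, "_labels.tif")))[1, 1, , ]
    lab <- matrix(as.integer(round(lab * 65535)), nrow(lab), ncol(lab))
    rows[[length(rows) + 1]] <-
      classify_cell(obj[obj$cell_id == id, ], lab, cp, cell_id = id)
  }
  classes <- do.call(rbind, rows)
  .write_csv(classes, file.path(out_dir, "classes.csv"), hash)
  note("classes.csv")
  classes$condition <- "simulated"; classes$replicate <- 1L
  .write_csv(summarize_classes(classes),
             file.path(out_dir, "class_summary.csv"), hash)
  note("class_summary.csv")
  invisible(NULL)
}

.stage_tether <- function(cfg, out_dir, hash, note) {
  tp <- .trk_params_from(cfg)
  st <- read_stack(file.path(out_dir, "timelapse.tif"))
  foci <- lapply(seq_len(dim(st)[1]), function(t) st[t, 1, , ])
  mito <- lapply(seq_len(dim(st)[1]), function(t) st[t, 2, , ])
  events <- track_tethering(foci, mito, tp)
  .write_csv(events, file.path(out_dir, "events.csv"), hash); note("events.csv")
  if (nrow(events)) {
    .write_csv(tether_stats(events)$summary,
               file.path(out_dir, "tether_summary.csv"), hash)
    note("tether_summary.csv")
  }
  invisible(NULL)
}

.stage_contacts <- function(cfg, out_dir, hash, note) {
  scene <- read_scene_csv(file.path(out_dir, "em_scene.csv"),
                          nm_per_unit = cfg$calibration$nm_per_unit)
  res <- analyze_contacts(scene, step_nm = cfg$contacts$step_nm,
                          max_gap_nm = cfg$contacts$max_gap_nm,
                          gap_stat = cfg$contacts$gap_stat)
  .write_csv(res$contacts, file.path(out_dir, "contacts.csv"), hash)
  .write_csv(res$summary, file.path(out_dir, "contact_summary.csv"), hash)
  note("contacts.csv"); note("contact_summary.csv")
  invisible(NULL)
}

.stage_fusion <- function(cfg, out_dir, hash, note) {
  frames4 <- read_stack(file.path(out_dir, "pagfp.tif"))
  frames <- lapply(seq_len(dim(frames4)[1]), function(t) frames4[t, 1, , ])
  mask <- read_stack(file.path(out_dir, "pagfp_mask.tif"))[1, 1, , ]
  roi <- jsonlite::read_json(file.path(out_dir, "pagfp_roi.json"),
                             simplifyVector = TRUE)
  curve <- measure_spread(frames, mask, roi,
                          timepoints_min = cfg$fusion$timepoints_min,
                          threshold_frac = cfg$fusion$threshold_frac,
                          cell_id = "pagfp")
  .write_csv(curve, file.path(out_dir, "fusion_curves.csv"), hash)
  note("fusion_curves.csv")
  invisible(NULL)
}
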