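# Ground-truthed synthetic-data generators for the four experimental
# modalities the pipeline quantifies: single-cell mitochondrial network
# images, two-channel tethering time-lapses, traced EM scenes, and
# photoactivatable-GFP spread series. Every generator is deterministic given
# its spec and seed, and returns the ground truth alongside the rendered data.

# ---- morphology images ------------------------------------------------------

#' Specification for a synthetic mitochondrial-network image
#'
#' Describes one cell as a mixture of round blobs and curved tubules, with
#' optional hyperfused (all objects merged into one reticular component) or
#' collapsed (objects concentrated around a perinuclear focus) layouts.
#'
#' @param n_tubules,n_blobs object counts.
#' @param tubule_length_px length 2 vector `c(mean, sd)` of tubule lengths.
#' @param tubule_width_px tubule width (px).
#' @param blob_radius_px blob radius (px).
#' @param image_size_px `c(rows, cols)`.
#' @param psf_sigma_px Gaussian PSF sigma; 0 disables blurring.
#' @param noise list with `gaussian_sd` (read noise) and `poisson_scale`
#'   (photon count at intensity 1; larger = less shot noise; 0 disables).
#' @param hyperfused if `TRUE`, render one connected reticular network.
#' @param collapsed if `TRUE`, concentrate objects in a disc of radius
#'   0.15 x image width around the image center.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return object of class `morphology_spec`.
#' @export
morphology_spec <- function(n_tubules = 0, n_blobs = 0,
                            tubule_length_px = c(60, 10),
                            tubule_width_px = 5, blob_radius_px = 5,
                            image_size_px = c(320, 320), psf_sigma_px = 1,
                            noise = list(gaussian_sd = 0.01, poisson_scale = 400),
                            hyperfused = FALSE, collapsed = FALSE, seed = 1) {
  stopifnot(n_tubules >= 0, n_blobs >= 0, n_tubules + n_blobs >= 0,
            all(tubule_length_px > 0) || n_tubules == 0,
            tubule_width_px > 0, blob_radius_px > 0,
            length(image_size_px) == 2, all(image_size_px > 0),
            psf_sigma_px >= 0, noise$gaussian_sd >= 0, noise$poisson_scale >= 0)
  if (hyperfused && collapsed) stop("hyperfused and collapsed are mutually exclusive")
  structure(list(n_tubules = n_tubules, n_blobs = n_blobs,
                 tubule_length_px = tubule_length_px,
                 tubule_width_px = tubule_width_px,
                 blob_radius_px = blob_radius_px,
                 image_size_px = as.integer(image_size_px),
                 psf_sigma_px = psf_sigma_px, noise = noise,
                 hyperfused = hyperfused, collapsed = collapsed,
                 seed = as.integer(seed)),
            class = "morphology_spec")
}

# second-central-moment ellipse axis ratio of a pixel set
.pixel_moment_ar <- function(r, c) {
  if (length(r) < 2) return(1)
  mr <- mean(r); mc <- mean(c)
  urr <- mean((r - mr)^2); ucc <- mean((c - mc)^2); urc <- mean((r - mr) * (c - mc))
  tr <- urr + ucc
  det <- urr * ucc - urc^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l2 <= 0) return(Inf)
  sqrt(l1 / l2)
}

#' Generate a synthetic mitochondrial-network image with ground truth
#'
#' Renders the objects described by a [morphology_spec()], applies the PSF
#' and noise model, and returns per-object true shape parameters measured on
#' the noise-free mask plus the network-class label implied by the spec.
#' Objects never touch the image border and never overlap (bounded retries;
#' a spec that cannot be placed raises an error).
#'
#' @param spec a [morphology_spec()].
#' @return list with `image` (noisy intensity matrix in \[0, 1\]), `mask`
#'   (noise-free binary matrix), `labels` (true per-object label matrix),
#'   `objects` (data.frame: object_id, type, centroid_row, centroid_col,
#'   area_px, true_ar), `class` (true network class), and `spec`.
#' @export
gen_morphology_image <- function(spec) {
  stopifnot(inherits(spec, "morphology_spec"))
  with_seed(spec$seed, {
    dim <- spec$image_size_px
    labels <- matrix(0L, dim[1], dim[2])
    margin <- 4 + 2 * spec$psf_sigma_px
    placed <- list()  # capsules: list(a=, b=, rad=)
    objects <- list()

    if (spec$hyperfused) {
      n_nodes <- max(spec$n_tubules, 2) + 1
      span <- 0.75 * min(dim)
      ctr <- dim / 2
      # nodes are kept spread out so the reticulum spans the cell rather
      # than clumping around its centroid (a hyperfused network is
      # interconnected but not perinuclear-collapsed)
      min_sep <- max(2.5 * spec$tubule_width_px, 0.18 * span)
      nodes <- NULL
      tries <- 0
      while (is.null(nodes) || nrow(nodes) < n_nodes) {
        p <- ctr + stats::runif(2, -span / 2, span / 2)
        if (is.null(nodes) || all(sqrt(rowSums((nodes - rep(p, each = nrow(nodes)))^2)) >
                                  min_sep)) {
          nodes <- rbind(nodes, p)
        }
        tries <- tries + 1
        if (tries > 5000) stop("could not place hyperfused network nodes")
      }
      rownames(nodes) <- NULL
      d <- as.matrix(stats::dist(nodes))
      g <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE, mode = "undirected")
      mst <- igraph::mst(g)
      for (e in seq_len(igraph::ecount(mst))) {
        ends <- igraph::ends(mst, e)
        px <- .tube_pixels(dim, rbind(nodes[as.integer(ends[1]), ],
                                      nodes[as.integer(ends[2]), ]),
                           spec$tubule_width_px)
        labels[px] <- 1L
      }
      idx <- which(labels == 1L)
      rr <- (idx - 1L) %% dim[1] + 1L; cc <- (idx - 1L) %/% dim[1] + 1L
      objects[[1]] <- data.frame(object_id = 1L, type = "network",
                                 centroid_row = mean(rr), centroid_col = mean(cc),
                                 area_px = length(idx),
                                 true_ar = .pixel_moment_ar(rr, cc))
      true_class <- "Hyperfused"
    } else {
      types <- c(rep("tubule", spec$n_tubules), rep("blob", spec$n_blobs))
      next_id <- 0L
      for (ty in types) {
        ok <- FALSE
        for (try in seq_len(500)) {
          if (spec$collapsed) {
            rad_place <- 0.15 * dim[2]
            ang <- stats::runif(1, 0, 2 * pi)
            rho <- rad_place * sqrt(stats::runif(1))
            center <- dim / 2 + rho * c(cos(ang), sin(ang))
          } else {
            center <- c(stats::runif(1, margin, dim[1] - margin),
                        stats::runif(1, margin, dim[2] - margin))
          }
          if (ty == "tubule") {
            len <- max(10, stats::rnorm(1, spec$tubule_length_px[1],
                                        spec$tubule_length_px[2]))
            th <- stats::runif(1, 0, 2 * pi)
            u <- c(cos(th), sin(th))
            a <- center - len / 2 * u; b <- center + len / 2 * u
            bow <- stats::runif(1, -0.15, 0.15) * len
            ctrl <- center + bow * c(-u[2], u[1])
            rad <- spec$tubule_width_px / 2 + abs(bow) / 2 + 1
          } else {
            a <- b <- center
            rad <- spec$blob_radius_px + 1
          }
          lo <- pmin(a, b) - rad; hi <- pmax(a, b) + rad
          if (any(lo < margin) || hi[1] > dim[1] - margin || hi[2] > dim[2] - margin) next
          # clearance wide enough that the PSF cannot bridge neighbours at
          # threshold; collapsed layouts pack tighter (clumping, not object
          # separation, is what they exercise)
          clearance <- if (spec$collapsed) 2 else 4 + 2 * spec$psf_sigma_px
          clash <- FALSE
          for (p in placed) {
            if (.seg_dist(a, b, p$a, p$b) < rad + p$rad + clearance) { clash <- TRUE; break }
          }
          if (clash) next
          next_id <- next_id + 1L
          if (ty == "tubule") {
            pts <- .bezier_points(a, ctrl, b, max(16, ceiling(2 * len)))
            px <- .tube_pixels(dim, pts, spec$tubule_width_px)
          } else {
            px <- .disc_pixels(dim, center[1], center[2], spec$blob_radius_px)
          }
          labels[px] <- next_id
          rr <- (px - 1L) %% dim[1] + 1L; cc <- (px - 1L) %/% dim[1] + 1L
          objects[[next_id]] <- data.frame(object_id = next_id, type = ty,
                                           centroid_row = mean(rr),
                                           centroid_col = mean(cc),
                                           area_px = length(px),
                                           true_ar = .pixel_moment_ar(rr, cc))
          placed[[length(placed) + 1]] <- list(a = a, b = b, rad = rad)
          ok <- TRUE
          break
        }
        if (!ok) stop("could not place all objects without overlap; ",
                      "reduce counts or enlarge the image")
      }
      true_class <- if (spec$collapsed) {
        "Collapsed"
      } else {
        n <- spec$n_tubules + spec$n_blobs
        tf <- if (n > 0) spec$n_tubules / n else 0
        if (n == 0) "Intermediate"
        else if (tf > 0.9) "Elongated"
        else if (1 - tf > 0.9) "Fragmented"
        else "Intermediate"
      }
    }

    mask <- matrix(as.numeric(labels > 0L), dim[1], dim[2])
    img <- 0.8 * mask
    if (spec$psf_sigma_px > 0) img <- .gauss_smooth(img, spec$psf_sigma_px)
    if (spec$noise$poisson_scale > 0) {
      img <- matrix(stats::rpois(length(img), img * spec$noise$poisson_scale) /
                      spec$noise$poisson_scale, dim[1], dim[2])
    }
    if (spec$noise$gaussian_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise$gaussian_sd),
                          dim[1], dim[2])
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    list(image = img, mask = mask, labels = labels,
         objects = do.call(rbind, objects), class = true_class, spec = spec)
  })
}

# ---- tethering time-lapses --------------------------------------------------

#' Specification for a synthetic two-channel tethering time-lapse
#'
#' Each programmed event is a pair of adjacent mitochondria joined by one
#' bright focus for its dwell time; fused events merge the pair in the
#' mitochondria channel afterwards, separated events simply lose the focus.
#'
#' @param n_frames number of frames (default 100, i.e. 5 min at 3 s/frame).
#' @param dt_s frame interval in seconds (default 3).
#' @param n_events number of programmed tethering events.
#' @param dwell_dist dwell-time distribution: `list(name = "point", value = s)`
#'   or `list(name = "shifted_exp", shift = s, mean = s)` (shift plus an
#'   exponential of the given mean).
#' @param p_fusion probability an event ends in fusion (vs separation).
#' @param foci_intensity peak intensity of a focus.
#' @param mito_radius_px radius of each mitochondrion disc.
#' @param jitter_sd_px per-frame Gaussian jitter of the focus position.
#' @param max_start_frame latest allowed (uniformly drawn) event start frame.
#' @param seed integer seed.
#' @return object of class `timelapse_spec`.
#' @export
timelapse_spec <- function(n_frames = 100, dt_s = 3, n_events = 5,
                           dwell_dist = list(name = "point", value = 30),
                           p_fusion = 0.5, foci_intensity = 0.9,
                           mito_radius_px = 6, jitter_sd_px = 0.5,
                           max_start_frame = 5, seed = 1) {
  stopifnot(n_frames >= 2, dt_s > 0, n_events >= 1,
            p_fusion >= 0, p_fusion <= 1,
            dwell_dist$name %in% c("point", "shifted_exp"))
  if (dwell_dist$name == "point" &&
      round(dwell_dist$value / dt_s) + max_start_frame + 1 > n_frames) {
    stop("requested event durations do not fit in n_frames")
  }
  structure(list(n_frames = as.integer(n_frames), dt_s = dt_s,
                 n_events = as.integer(n_events), dwell_dist = dwell_dist,
                 p_fusion = p_fusion, foci_intensity = foci_intensity,
                 mito_radius_px = mito_radius_px, jitter_sd_px = jitter_sd_px,
                 max_start_frame = as.integer(max_start_frame),
                 seed = as.integer(seed)),
            class = "timelapse_spec")
}

.sample_dwell <- function(dist, n) {
  switch(dist$name,
         point = rep(dist$value, n),
         shifted_exp = dist$shift + stats::rexp(n, rate = 1 / dist$mean))
}

# 2D Gaussian stamp of a focus at sub-pixel position (r0, c0)
.stamp_spot <- function(frame, r0, c0, amp, sigma = 1.5) {
  rad <- 4L
  rr <- max(1L, round(r0) - rad):min(nrow(frame), round(r0) + rad)
  cc <- max(1L, round(c0) - rad):min(ncol(frame), round(c0) + rad)
  g <- amp * outer(exp(-(rr - r0)^2 / (2 * sigma^2)),
                   exp(-(cc - c0)^2 / (2 * sigma^2)))
  frame[rr, cc] <- pmax(frame[rr, cc], g)
  frame
}

#' Generate a synthetic tethering time-lapse with a true event table
#'
#' @param spec a [timelapse_spec()].
#' @return list with `foci` and `mito` (lists of frame matrices), `truth`
#'   (data.frame: event_id, junction_row, junction_col, start_frame,
#'   end_frame, duration_s, outcome — frames are 1-based), and `spec`.
#'   Mitochondria pairs sit in disjoint tiles; a fused pair is bridged into
#'   one component from the frame after the event ends.
#' @export
gen_timelapse <- function(spec) {
  stopifnot(inherits(spec, "timelapse_spec"))
  with_seed(spec$seed, {
    tile <- 48L
    gside <- ceiling(sqrt(spec$n_events))
    dim <- c(gside * tile, gside * tile)
    rad <- spec$mito_radius_px
    off <- rad + 2          # half-gap: centers at junction +/- off, 3 px gap
    base <- .blank_image(dim)
    junctions <- matrix(0, spec$n_events, 2)
    pair_px <- vector("list", spec$n_events)
    for (e in seq_len(spec$n_events)) {
      tr <- (e - 1) %/% gside; tc <- (e - 1) %% gside
      r0 <- tr * tile + tile / 2; c0 <- tc * tile + tile / 2
      junctions[e, ] <- c(r0, c0)
      pL <- .disc_pixels(dim, r0, c0 - off, rad)
      pR <- .disc_pixels(dim, r0, c0 + off, rad)
      base[pL] <- 0.8; base[pR] <- 0.8
      pair_px[[e]] <- list(L = pL, R = pR)
    }

    starts <- sample.int(spec$max_start_frame + 1L, spec$n_events,
                         replace = TRUE) - 1L          # 0-based start offsets
    dwell <- .sample_dwell(spec$dwell_dist, spec$n_events)
    k <- pmax(1L, as.integer(round(dwell / spec$dt_s)))  # tethered span in frames
    outcome <- ifelse(stats::runif(spec$n_events) < spec$p_fusion,
                      "fused", "separated")
    last <- spec$n_frames - 1L                            # 0-based last frame
    ends <- starts + k
    over <- ends >= last                                  # runs to stack end
    outcome[over] <- "censored"
    ends[over] <- last
    truth <- data.frame(event_id = seq_len(spec$n_events),
                        junction_row = junctions[, 1],
                        junction_col = junctions[, 2],
                        start_frame = starts + 1L, end_frame = ends + 1L,
                        duration_s = (ends - starts) * spec$dt_s,
                        outcome = outcome)

    bridge_px <- lapply(seq_len(spec$n_events), function(e) {
      if (outcome[e] != "fused") return(NULL)
      .tube_pixels(dim, rbind(c(junctions[e, 1], junctions[e, 2] - off),
                              c(junctions[e, 1], junctions[e, 2] + off)),
                   width = rad)
    })

    mito <- vector("list", spec$n_frames)
    foci <- vector("list", spec$n_frames)
    cur <- base
    merge_at <- ifelse(outcome == "fused", ends + 1L, NA_integer_)
    for (t0 in 0:last) {
      newly <- which(!is.na(merge_at) & merge_at == t0)
      for (e in newly) { cur[bridge_px[[e]]] <- 0.8 }
      mito[[t0 + 1L]] <- cur
      fr <- .blank_image(dim)
      active <- which(starts <= t0 & t0 <= ends)
      for (e in active) {
        jit <- stats::rnorm(2, 0, spec$jitter_sd_px)
        fr <- .stamp_spot(fr, junctions[e, 1] + jit[1], junctions[e, 2] + jit[2],
                          spec$foci_intensity)
      }
      foci[[t0 + 1L]] <- fr
    }
    list(foci = foci, mito = mito, truth = truth, spec = spec)
  })
}

# ---- traced EM scenes -------------------------------------------------------

#' Specification for a synthetic traced EM scene
#'
#' Mitochondria are circles (fine polygons) in physical nm coordinates; each
#' ER segment is an arc held at a programmed stand-off distance from its
#' target mitochondrion's surface, or a free segment far from every
#' mitochondrion when `target` is `NA`.
#'
#' @param n_mito number of mitochondria.
#' @param mito_radius_nm circle radius (nm).
#' @param er_segments data.frame with columns `target` (mitochondrion index
#'   or `NA`), `standoff_nm` (>= 0) and `arc_length_nm` (> 0, length of the
#'   ER trace itself).
#' @param nm_per_unit calibration: nm per coordinate unit of the emitted
#'   scene (default 1, i.e. coordinates are nm).
#' @param seed integer seed.
#' @return object of class `em_scene_spec`.
#' @export
em_scene_spec <- function(n_mito = 2, mito_radius_nm = 250,
                          er_segments = data.frame(target = c(1, 2),
                                                   standoff_nm = c(20, 45),
                                                   arc_length_nm = c(300, 200)),
                          nm_per_unit = 1, seed = 1) {
  stopifnot(n_mito >= 1, mito_radius_nm > 0, nm_per_unit > 0,
            all(c("target", "standoff_nm", "arc_length_nm") %in% names(er_segments)),
            all(er_segments$standoff_nm >= 0), all(er_segments$arc_length_nm > 0),
            all(is.na(er_segments$target) |
                  (er_segments$target >= 1 & er_segments$target <= n_mito)))
  structure(list(n_mito = as.integer(n_mito), mito_radius_nm = mito_radius_nm,
                 er_segments = er_segments, nm_per_unit = nm_per_unit,
                 seed = as.integer(seed)),
            class = "em_scene_spec")
}

#' Generate a traced EM scene with a true contact table
#'
#' ER segments with stand-off <= 60 nm appear in the truth table with their
#' programmed length, GAP and target; farther segments appear only in the
#' scene. Arcs targeting the same mitochondrion occupy disjoint angular
#' sectors so programmed contacts never merge.
#'
#' @param spec an [em_scene_spec()].
#' @return list with `scene` (data.frame in the traced-annotation layout:
#'   cell_id, object_type, object_id, vertex_index, x_nm, y_nm — coordinates
#'   divided by `nm_per_unit`), `truth_contacts`, `truth_summary`, `spec`.
#' @export
gen_em_scene <- function(spec) {
  stopifnot(inherits(spec, "em_scene_spec"))
  with_seed(spec$seed, {
    r <- spec$mito_radius_nm
    seg <- spec$er_segments
    max_off <- if (nrow(seg)) max(seg$standoff_nm, 0) else 0
    spacing <- 2 * r + 2 * max_off + 400
    gside <- ceiling(sqrt(spec$n_mito))
    centers <- t(vapply(seq_len(spec$n_mito), function(i) {
      c(((i - 1) %% gside) * spacing, ((i - 1) %/% gside) * spacing)
    }, numeric(2)))

    nv <- 256L
    ang <- seq(0, 2 * pi, length.out = nv + 1L)[-(nv + 1L)]
    rows <- list()
    for (i in seq_len(spec$n_mito)) {
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = 1L, object_type = "mito", object_id = i,
        vertex_index = seq_len(nv),
        x_nm = centers[i, 1] + r * cos(ang),
        y_nm = centers[i, 2] + r * sin(ang))
    }

    # disjoint angular sectors per target mitochondrion
    sector_cursor <- stats::runif(spec$n_mito, 0, 2 * pi)
    sector_init <- sector_cursor
    truth <- list()
    free_y <- min(centers[, 2]) - r - max_off - 300
    er_id <- 0L
    for (j in seq_len(nrow(seg))) {
      er_id <- er_id + 1L
      tgt <- seg$target[j]; g <- seg$standoff_nm[j]; L <- seg$arc_length_nm[j]
      if (is.na(tgt)) {
        free_y <- free_y - 250
        x0 <- min(centers[, 1]) - r - max_off - 300
        n_v <- max(8L, ceiling(L / 3))
        xs <- seq(x0, x0 + L, length.out = n_v)
        rows[[length(rows) + 1]] <- data.frame(
          cell_id = 1L, object_type = "er", object_id = er_id,
          vertex_index = seq_len(n_v), x_nm = xs, y_nm = rep(free_y, n_v))
        next
      }
      theta <- L / (r + g)
      if (theta >= 2 * pi) stop("ER arc longer than its orbit; shorten arc_length_nm")
      a0 <- sector_cursor[tgt] + stats::runif(1, 0.15, 0.35)
      sector_cursor[tgt] <- a0 + theta
      n_v <- max(8L, ceiling(L / 3))
      aa <- seq(a0, a0 + theta, length.out = n_v)
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = 1L, object_type = "er", object_id = er_id,
        vertex_index = seq_len(n_v),
        x_nm = centers[tgt, 1] + (r + g) * cos(aa),
        y_nm = centers[tgt, 2] + (r + g) * sin(aa))
      if (g <= 60) {
        truth[[length(truth) + 1]] <- data.frame(
          er_id = er_id, mito_id = tgt, gap_nm = g, length_nm = L,
          gap_bin = .gap_bin_label(g), projected_arc_nm = theta * r)
      }
    }
    if (any(sector_cursor - sector_init > 2 * pi)) {
      stop("ER arcs exceed one turn around a mitochondrion; shorten arc_length_nm")
    }
    scene <- do.call(rbind, rows)
    scene$x_nm <- scene$x_nm / spec$nm_per_unit
    scene$y_nm <- scene$y_nm / spec$nm_per_unit
    truth_contacts <- if (length(truth)) do.call(rbind, truth) else
      data.frame(er_id = integer(0), mito_id = integer(0), gap_nm = numeric(0),
                 length_nm = numeric(0), gap_bin = character(0),
                 projected_arc_nm = numeric(0))
    perim <- 2 * nv * r * sin(pi / nv)  # polygon perimeter of the circle trace
    truth_summary <- data.frame(
      n_contacts = nrow(truth_contacts),
      contacts_per_mito = nrow(truth_contacts) / spec$n_mito,
      mean_contact_length_nm = if (nrow(truth_contacts)) mean(truth_contacts$length_nm) else NA_real_,
      mean_mito_perimeter_nm = perim,
      percent_perimeter_covered =
        100 * sum(truth_contacts$projected_arc_nm) / (spec$n_mito * perim))
    list(scene = scene, truth_contacts = truth_contacts,
         truth_summary = truth_summary, spec = spec)
  })
}

.gap_bin_label <- function(g) {
  ifelse(g < 15, "[0,15)", ifelse(g < 30, "[15,30)", "[30,60]"))
}

# ---- PA-GFP spread series ---------------------------------------------------

#' Specification for a synthetic photoactivation spread series
#'
#' Mitochondrial components are rendered as bars of programmed area; the
#' activated GFP signal fills a programmed, non-decreasing fraction of the
#' activated component at each timepoint, starting from the ROI fraction.
#'
#' @param component_areas_px areas (px) of the connected components.
#' @param activated_component index of the photoactivated component.
#' @param roi_fraction fraction (0, 1] of that component initially activated.
#' @param timepoints_min acquisition timepoints in minutes (default 0, 5, 10).
#' @param spread_fractions fraction of the component filled at each
#'   timepoint; non-decreasing, first value equal to `roi_fraction`.
#' @param seed integer seed.
#' @return object of class `pagfp_spec`.
#' @export
pagfp_spec <- function(component_areas_px = c(600, 400, 300),
                       activated_component = 1, roi_fraction = 0.2,
                       timepoints_min = c(0, 5, 10),
                       spread_fractions = c(0.2, 0.6, 1.0), seed = 1) {
  stopifnot(all(component_areas_px > 0),
            length(timepoints_min) == length(spread_fractions),
            all(spread_fractions > 0), all(spread_fractions <= 1),
            roi_fraction > 0, roi_fraction <= 1)
  if (activated_component < 1 || activated_component > length(component_areas_px)) {
    stop("activated_component out of range")
  }
  if (any(diff(spread_fractions) < -1e-12)) {
    stop("spread_fractions must be non-decreasing")
  }
  if (abs(spread_fractions[1] - roi_fraction) > 1e-9) {
    stop("spread_fractions[1] must equal roi_fraction")
  }
  structure(list(component_areas_px = component_areas_px,
                 activated_component = as.integer(activated_component),
                 roi_fraction = roi_fraction, timepoints_min = timepoints_min,
                 spread_fractions = spread_fractions, seed = as.integer(seed)),
            class = "pagfp_spec")
}

#' Generate a photoactivation spread series with true normalized areas
#'
#' @param spec a [pagfp_spec()].
#' @return list with `mask` (binary mitochondria mask), `frames` (list of
#'   GFP intensity matrices, one per timepoint), `roi` (list rmin, rmax,
#'   cmin, cmax), `timepoints_min`, `truth` (data.frame: timepoint_min,
#'   true_normalized_area = spread/spread at t0), and `spec`.
#' @export
gen_pagfp_series <- function(spec) {
  stopifnot(inherits(spec, "pagfp_spec"))
  with_seed(spec$seed, {
    h <- 10L; gap <- 8L; marg <- 6L
    lens <- pmax(2L, as.integer(round(spec$component_areas_px / h)))
    W <- max(lens) + 2L * marg
    H <- length(lens) * (h + gap) + marg
    mask <- matrix(0, H, W)
    for (i in seq_along(lens)) {
      r0 <- marg + (i - 1L) * (h + gap)
      mask[r0:(r0 + h - 1L), marg:(marg + lens[i] - 1L)] <- 1
    }
    a <- spec$activated_component
    r0 <- marg + (a - 1L) * (h + gap)
    bar_rows <- r0:(r0 + h - 1L)
    bar_cols <- marg:(marg + lens[a] - 1L)
    # bar pixels ordered along the bar axis so any activated fraction is
    # realized to single-pixel precision (no whole-column quantization)
    bar_idx <- as.integer(outer(bar_rows, (bar_cols - 1L) * H, "+"))
    n_bar <- length(bar_idx)
    n_act0 <- max(1L, round(spec$roi_fraction * n_bar))
    act_cols0 <- unique((bar_idx[seq_len(n_act0)] - 1L) %/% H + 1L)
    roi <- list(rmin = min(bar_rows), rmax = max(bar_rows),
                cmin = min(act_cols0), cmax = max(act_cols0))
    frames <- lapply(spec$spread_fractions, function(f) {
      fr <- 0.02 * mask        # faint pre-activation baseline on all mitochondria
      fr[bar_idx[seq_len(max(1L, round(f * n_bar)))]] <- 0.9
      fr + matrix(stats::rnorm(length(fr), 0, 0.004), H, W)
    })
    truth <- data.frame(timepoint_min = spec$timepoints_min,
                        true_normalized_area =
                          spec$spread_fractions / spec$spread_fractions[1])
    list(mask = mask, frames = frames, roi = roi,
         timepoints_min = spec$timepoints_min, truth = truth, spec = spec)
  })
}
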