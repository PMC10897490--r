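# ER-mitochondria contact-site geometry from traced outlines: ER polylines
# are resampled at uniform arc-length steps, each sample is assigned its
# distance to (and projection onto) the nearest mitochondrial surface,
# maximal runs at <= 60 nm become contact sites with an arc length and a GAP
# distance, GAPs are binned into 0-15 / 15-30 / 30-60 nm, and per-cell
# summaries report contacts per mitochondrion and perimeter coverage.

#' Build an annotated scene from a traced-annotation table
#'
#' @param df data.frame with columns cell_id, object_type (`"mito"` or
#'   `"er"`), object_id, vertex_index, x_nm, y_nm. Mitochondria are closed
#'   polygons (the closing edge is implicit), ER traces open polylines.
#' @param nm_per_unit nm per coordinate unit (default 1).
#' @return list of class `annotated_scene` with `mito` and `er` (lists of
#'   n x 2 coordinate matrices in nm) and `cell_id`.
#' @export
as_scene <- function(df, nm_per_unit = 1) {
  stopifnot(all(c("object_type", "object_id", "vertex_index", "x_nm", "y_nm")
                %in% names(df)),
            nm_per_unit > 0)
  if (!all(is.finite(df$x_nm)) || !all(is.finite(df$y_nm))) {
    stop("scene coordinates must be finite")
  }
  get_objs <- function(type) {
    sub <- df[df$object_type == type, , drop = FALSE]
    lapply(split(sub, sub$object_id), function(o) {
      o <- o[order(o$vertex_index), ]
      cbind(x = o$x_nm, y = o$y_nm) * nm_per_unit
    })
  }
  mito <- get_objs("mito")
  if (!length(mito)) stop("scene contains no mitochondria")
  structure(list(mito = mito, er = get_objs("er"),
                 cell_id = if ("cell_id" %in% names(df)) df$cell_id[1] else NA),
            class = "annotated_scene")
}

#' Read a traced-annotation CSV into a scene
#' @param path CSV file in the [as_scene()] layout.
#' @inheritParams as_scene
#' @return an `annotated_scene`.
#' @export
read_scene_csv <- function(path, nm_per_unit = 1) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  as_scene(.read_csv(path), nm_per_unit)
}

# closed-polygon edge table with cumulative perimeter positions
.polygon_edges <- function(poly) {
  a <- poly
  b <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  len <- sqrt(rowSums((b - a)^2))
  list(a = a, b = b, len = len, cum0 = cumsum(c(0, len[-length(len)])),
       perimeter = sum(len))
}

# resample an open polyline at uniform arc-length steps
.resample_polyline <- function(pts, step) {
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))
  L <- sum(seglen)
  s <- seq(0, L, by = step)
  if (s[length(s)] < L - 1e-9) s <- c(s, L)
  cum <- cumsum(c(0, seglen))
  seg <- pmin(findInterval(s, cum, rightmost.closed = TRUE), nrow(pts) - 1)
  t <- (s - cum[seg]) / pmax(seglen[seg], 1e-12)
  xy <- pts[seg, , drop = FALSE] +
    (pts[seg + 1, , drop = FALSE] - pts[seg, , drop = FALSE]) * t
  list(s = s, xy = xy, length = L)
}

#' Sample an ER trace against the mitochondrial surfaces
#'
#' Resamples the polyline at uniform arc-length steps and, for every
#' sample, computes the Euclidean distance to the nearest mitochondrial
#' boundary (0 for points inside a mitochondrion), the identity of the
#' nearest mitochondrion, and the projection of the sample onto that
#' perimeter (as an arc-length coordinate, used for coverage).
#'
#' @param er_polyline n x 2 coordinate matrix (nm).
#' @param mito_polygons list of closed-polygon coordinate matrices (nm).
#' @param step_nm resampling step (default 5 nm).
#' @return data.frame: arc_pos_nm, dist_nm, mito_id, proj_arc_nm.
#' @export
sample_distances <- function(er_polyline, mito_polygons, step_nm = 5) {
  if (is.null(er_polyline) || nrow(er_polyline) < 2 || !length(mito_polygons)) {
    stop("need an ER polyline with >= 2 vertices and >= 1 mitochondrion")
  }
  stopifnot(step_nm > 0)
  rs <- .resample_polyline(er_polyline, step_nm)
  n <- nrow(rs$xy)
  best_d <- rep(Inf, n); best_m <- integer(n); best_proj <- numeric(n)
  for (m in seq_along(mito_polygons)) {
    ed <- .polygon_edges(mito_polygons[[m]])
    d2 <- rep(Inf, n); proj <- numeric(n)
    for (e in seq_along(ed$len)) {
      ab <- ed$b[e, ] - ed$a[e, ]
      len2 <- max(sum(ab^2), 1e-12)
      t <- pmin(1, pmax(0, ((rs$xy[, 1] - ed$a[e, 1]) * ab[1] +
                              (rs$xy[, 2] - ed$a[e, 2]) * ab[2]) / len2))
      dd <- (rs$xy[, 1] - (ed$a[e, 1] + t * ab[1]))^2 +
        (rs$xy[, 2] - (ed$a[e, 2] + t * ab[2]))^2
      upd <- dd < d2
      d2[upd] <- dd[upd]
      proj[upd] <- ed$cum0[e] + t[upd] * ed$len[e]
    }
    d <- sqrt(d2)
    inside <- pracma::inpolygon(rs$xy[, 1], rs$xy[, 2],
                                mito_polygons[[m]][, 1], mito_polygons[[m]][, 2])
    d[inside] <- 0
    upd <- d < best_d
    best_d[upd] <- d[upd]; best_m[upd] <- m; best_proj[upd] <- proj[upd]
  }
  data.frame(arc_pos_nm = rs$s, dist_nm = best_d, mito_id = best_m,
             proj_arc_nm = best_proj)
}

#' Extract contact sites from sampled distances
#'
#' Maximal contiguous runs of samples with distance at most `max_gap_nm`
#' and a constant nearest mitochondrion become one contact site each; a run
#' is split when the nearest mitochondrion changes, so each contact belongs
#' to exactly one mitochondrion. Contact length is the arc span of the run
#' (one sampling step for a single-sample run); the GAP is the mean (or,
#' optionally, minimum) sampled distance over the run.
#'
#' @param samples data.frame from [sample_distances()].
#' @param max_gap_nm contact threshold (default 60 nm).
#' @param gap_stat `"mean"` (default) or `"min"` reduction per contact.
#' @return data.frame: contact_id, mito_id, start_arc_nm, end_arc_nm,
#'   length_nm, gap_nm, gap_bin, n_samples; zero rows when nothing is in
#'   contact. Sample membership is attached as attribute `"contact_of"`
#'   (integer per sample, 0 = not in a contact).
#' @export
extract_contacts <- function(samples, max_gap_nm = 60,
                             gap_stat = c("mean", "min")) {
  gap_stat <- match.arg(gap_stat)
  step <- if (nrow(samples) > 1) stats::median(diff(samples$arc_pos_nm)) else 1
  ok <- samples$dist_nm <= max_gap_nm
  key <- ifelse(ok, samples$mito_id, 0L)
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  contact_of <- integer(nrow(samples))
  out <- list()
  cid <- 0L
  for (i in seq_along(r$values)) {
    if (r$values[i] == 0L) next
    cid <- cid + 1L
    ii <- starts[i]:ends[i]
    contact_of[ii] <- cid
    span <- samples$arc_pos_nm[ends[i]] - samples$arc_pos_nm[starts[i]]
    g <- if (gap_stat == "mean") mean(samples$dist_nm[ii]) else min(samples$dist_nm[ii])
    out[[cid]] <- data.frame(
      contact_id = cid, mito_id = r$values[i],
      start_arc_nm = samples$arc_pos_nm[starts[i]],
      end_arc_nm = samples$arc_pos_nm[ends[i]],
      length_nm = max(span, step), gap_nm = g,
      gap_bin = .gap_bin_label(g), n_samples = length(ii))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contact_id = integer(0), mito_id = integer(0),
               start_arc_nm = numeric(0), end_arc_nm = numeric(0),
               length_nm = numeric(0), gap_nm = numeric(0),
               gap_bin = character(0), n_samples = integer(0))
  attr(res, "contact_of") <- contact_of
  res
}

#' Count contacts per GAP bin
#'
#' Bins are half-open-left: \[0, 15), \[15, 30), and closed \[30, 60\]
#' (a GAP of exactly 15 falls in the middle bin). Counts always sum to the
#' number of contacts.
#'
#' @param contacts data.frame from [extract_contacts()].
#' @return named integer vector of counts for the three bins.
#' @export
bin_gaps <- function(contacts) {
  bins <- c("[0,15)", "[15,30)", "[30,60]")
  if (nrow(contacts) && any(contacts$gap_nm > 60 | contacts$gap_nm < 0)) {
    stop("contact GAP outside [0, 60] nm violates the contact definition")
  }
  counts <- table(factor(contacts$gap_bin, levels = bins))
  stats::setNames(as.integer(counts), bins)
}

# union length of circular intervals on a perimeter of length P
.circular_union <- function(intervals, P) {
  if (!nrow(intervals)) return(0)
  segs <- list()
  for (i in seq_len(nrow(intervals))) {
    a <- intervals[i, 1] %% P; b <- intervals[i, 2] %% P
    if (abs(intervals[i, 2] - intervals[i, 1]) >= P) return(P)
    if (a <= b) segs[[length(segs) + 1]] <- c(a, b)
    else { segs[[length(segs) + 1]] <- c(a, P); segs[[length(segs) + 1]] <- c(0, b) }
  }
  m <- do.call(rbind, segs)
  m <- m[order(m[, 1]), , drop = FALSE]
  tot <- 0; cur <- m[1, ]
  if (nrow(m) > 1) for (i in 2:nrow(m)) {
    if (m[i, 1] <= cur[2]) cur[2] <- max(cur[2], m[i, 2])
    else { tot <- tot + cur[2] - cur[1]; cur <- m[i, ] }
  }
  min(tot + cur[2] - cur[1], P)
}

#' Per-cell contact summary
#'
#' Contacts per mitochondrion, mean contact length, mean mitochondrial
#' perimeter, and the percentage of total mitochondrial perimeter covered
#' by ER contacts. Coverage projects every contact sample onto its nearest
#' perimeter point and measures the union of the projected arcs (overlapping
#' traces cannot push coverage past 100%).
#'
#' @param contacts data.frame from [extract_contacts()] (one or several ER
#'   traces; concatenate with [rbind()] preserving the `"contact_of"`
#'   attribute via [analyze_contacts()], or pass `samples` explicitly).
#' @param samples data.frame of the underlying samples with a `contact_id`
#'   column (0 = not in contact).
#' @param scene the `annotated_scene`.
#' @return one-row data.frame: cell_id, n_mito, n_contacts,
#'   contacts_per_mito, mean_contact_length_nm, mean_mito_perimeter_nm,
#'   percent_perimeter_covered.
#' @export
summarize_contacts <- function(contacts, samples, scene) {
  if (!length(scene$mito)) stop("scene contains no mitochondria")
  perims <- vapply(scene$mito, function(p) .polygon_edges(p)$perimeter, numeric(1))
  covered <- 0
  for (m in seq_along(scene$mito)) {
    ids <- contacts$contact_id[contacts$mito_id == m]
    if (!length(ids)) next
    ivals <- list()
    for (id in ids) {
      ss <- samples[samples$contact_id == id, , drop = FALSE]
      ss <- ss[order(ss$arc_pos_nm), ]
      if (nrow(ss) == 1) {
        step <- attr(contacts, "step_nm")
        if (is.null(step)) step <- 5
        ivals[[length(ivals) + 1]] <- c(ss$proj_arc_nm - step / 2,
                                        ss$proj_arc_nm + step / 2)
      } else {
        for (i in seq_len(nrow(ss) - 1)) {
          p1 <- ss$proj_arc_nm[i]; p2 <- ss$proj_arc_nm[i + 1]
          if (abs(p2 - p1) > perims[m] / 2) {
            # consecutive projections straddle the perimeter origin
            ivals[[length(ivals) + 1]] <- c(max(p1, p2), perims[m])
            ivals[[length(ivals) + 1]] <- c(0, min(p1, p2))
          } else {
            ivals[[length(ivals) + 1]] <- c(min(p1, p2), max(p1, p2))
          }
        }
      }
    }
    covered <- covered + .circular_union(do.call(rbind, ivals), perims[m])
  }
  data.frame(cell_id = scene$cell_id, n_mito = length(scene$mito),
             n_contacts = nrow(contacts),
             contacts_per_mito = nrow(contacts) / length(scene$mito),
             mean_contact_length_nm =
               if (nrow(contacts)) mean(contacts$length_nm) else NA_real_,
             mean_mito_perimeter_nm = mean(perims),
             percent_perimeter_covered = 100 * covered / sum(perims))
}

#' Full contact-site analysis of one annotated scene
#'
#' Runs [sample_distances()] over every ER trace, extracts contacts, bins
#' GAPs, and summarizes the cell.
#'
#' @param scene an `annotated_scene` from [as_scene()] / [read_scene_csv()].
#' @param step_nm resampling step (default 5 nm).
#' @param max_gap_nm contact threshold (default 60 nm).
#' @param gap_stat GAP reduction per contact, `"mean"` or `"min"`.
#' @return list with `contacts`, `samples` (with er_id and contact_id
#'   columns), `gap_bins`, and `summary`.
#' @export
analyze_contacts <- function(scene, step_nm = 5, max_gap_nm = 60,
                             gap_stat = "mean") {
  stopifnot(inherits(scene, "annotated_scene"))
  all_contacts <- list(); all_samples <- list()
  cid_off <- 0L
  for (k in seq_along(scene$er)) {
    ss <- sample_distances(scene$er[[k]], scene$mito, step_nm)
    cc <- extract_contacts(ss, max_gap_nm, gap_stat)
    ss$er_id <- k
    ss$contact_id <- ifelse(attr(cc, "contact_of") > 0L,
                            attr(cc, "contact_of") + cid_off, 0L)
    if (nrow(cc)) cc$contact_id <- cc$contact_id + cid_off
    cid_off <- cid_off + nrow(cc)
    all_contacts[[k]] <- cc
    all_samples[[k]] <- ss
  }
  contacts <- if (length(all_contacts)) do.call(rbind, all_contacts) else
    extract_contacts(data.frame(arc_pos_nm = numeric(0), dist_nm = numeric(0),
                                mito_id = integer(0), proj_arc_nm = numeric(0)))
  samples <- if (length(all_samples)) do.call(rbind, all_samples) else
    data.frame()
  attr(contacts, "step_nm") <- step_nm
  rownames(contacts) <- NULL
  list(contacts = contacts, samples = samples, gap_bins = bin_gaps(contacts),
       summary = summarize_contacts(contacts, samples, scene))
}
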