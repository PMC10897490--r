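# Tethering-event analysis for two-channel time-lapses: detect bright foci
# in the foci channel, link them into tracks by nearest-neighbor assignment
# with gap closing, open a tethering event while a focus touches two
# mitochondria, close it at separation or fusion, filter events by the
# strict "> 15 s" dwell rule, and summarize durations and fusion outcomes.

#' Tracking and event-extraction parameters
#'
#' @param spot_sigma_px Gaussian scale of a focus; used for matched-filter
#'   smoothing and as the minimum separation between detections.
#' @param spot_threshold minimum smoothed intensity of a detection.
#' @param max_link_px maximum frame-to-frame displacement when linking.
#' @param max_gap_frames frames a track may vanish and still be continued
#'   (default 1).
#' @param dt_s frame interval in seconds (default 3).
#' @param min_event_s events must last strictly longer than this to be
#'   reported (default 15 s, excluding kiss-and-run contacts).
#' @param adjacency_radius_px a focus "tethers" the mitochondria whose
#'   pixels lie within this distance of its center (default 3).
#' @param fusion_confirm_frames frames the merged object must persist after
#'   the event for a fused call (default 2, guarding against transient
#'   touching).
#' @return object of class `tracking_params`.
#' @export
tracking_params <- function(spot_sigma_px = 1.5, spot_threshold = 0.3,
                            max_link_px = 5, max_gap_frames = 1, dt_s = 3,
                            min_event_s = 15, adjacency_radius_px = 3,
                            fusion_confirm_frames = 2) {
  stopifnot(spot_sigma_px > 0, max_link_px > 0, max_gap_frames >= 0,
            dt_s > 0, min_event_s >= 0, adjacency_radius_px > 0,
            fusion_confirm_frames >= 1)
  structure(list(spot_sigma_px = spot_sigma_px, spot_threshold = spot_threshold,
                 max_link_px = max_link_px,
                 max_gap_frames = as.integer(max_gap_frames), dt_s = dt_s,
                 min_event_s = min_event_s,
                 adjacency_radius_px = adjacency_radius_px,
                 fusion_confirm_frames = as.integer(fusion_confirm_frames)),
            class = "tracking_params")
}

#' Detect foci in one frame
#'
#' Matched-filter detection: the frame is smoothed with a Gaussian of the
#' spot scale, local maxima above threshold become candidates, and centers
#' are refined to sub-pixel precision by an intensity-weighted centroid.
#' No two returned spots are closer than `spot_sigma_px`.
#'
#' @param frame 2D numeric matrix (foci channel).
#' @param params a [tracking_params()].
#' @return data.frame with columns row, col (sub-pixel, 1-based), intensity;
#'   zero rows when nothing is detected.
#' @export
detect_foci <- function(frame, params = tracking_params()) {
  # smoothing is an average, so it cannot raise the maximum above threshold
  if (max(frame) <= params$spot_threshold) {
    return(data.frame(row = numeric(0), col = numeric(0), intensity = numeric(0)))
  }
  sm <- .gauss_smooth(frame, params$spot_sigma_px)
  cand <- .local_max_at(sm, which(sm > params$spot_threshold))
  if (!length(cand)) {
    return(data.frame(row = numeric(0), col = numeric(0), intensity = numeric(0)))
  }
  rr <- (cand - 1L) %% nrow(frame) + 1L
  cc <- (cand - 1L) %/% nrow(frame) + 1L
  inten <- sm[cand]
  ord <- order(-inten)
  rr <- rr[ord]; cc <- cc[ord]; inten <- inten[ord]
  keep <- rep(TRUE, length(rr))
  for (i in seq_along(rr)) {
    if (!keep[i]) next
    if (i < length(rr)) {
      later <- (i + 1):length(rr)
      too_close <- (rr[later] - rr[i])^2 + (cc[later] - cc[i])^2 <
        params$spot_sigma_px^2
      keep[later][too_close] <- FALSE
    }
  }
  rr <- rr[keep]; cc <- cc[keep]; inten <- inten[keep]
  w <- 2L
  ref <- vapply(seq_along(rr), function(i) {
    rs <- max(1L, rr[i] - w):min(nrow(frame), rr[i] + w)
    cs <- max(1L, cc[i] - w):min(ncol(frame), cc[i] + w)
    patch <- sm[rs, cs, drop = FALSE]
    patch <- pmax(patch - min(patch), 0)
    s <- sum(patch)
    if (s == 0) return(c(rr[i], cc[i]))
    c(sum(rowSums(patch) * rs) / s, sum(colSums(patch) * cs) / s)
  }, numeric(2))
  data.frame(row = ref[1, ], col = ref[2, ], intensity = inten)
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbor assignment: in each frame, the closest
#' (track, spot) pairs within `max_link_px` are matched first; unmatched
#' spots start new tracks; a track missing for at most `max_gap_frames`
#' frames is still eligible (gap closing). Each spot joins at most one track.
#'
#' @param spots list of per-frame data.frames from [detect_foci()], in
#'   temporal order.
#' @param params a [tracking_params()].
#' @return data.frame with columns track_id, frame (1-based), row, col,
#'   intensity.
#' @export
link_tracks <- function(spots, params = tracking_params()) {
  active <- data.frame(track_id = integer(0), row = numeric(0),
                       col = numeric(0), last_frame = integer(0))
  rows <- list()
  next_id <- 0L
  for (t in seq_along(spots)) {
    sp <- spots[[t]]
    n_sp <- if (is.null(sp)) 0L else nrow(sp)
    assigned_sp <- rep(FALSE, n_sp)
    if (n_sp > 0 && nrow(active) > 0) {
      elig <- which(t - active$last_frame <= params$max_gap_frames + 1L)
      if (length(elig)) {
        d <- outer(active$row[elig], sp$row, "-")^2 +
          outer(active$col[elig], sp$col, "-")^2
        d <- sqrt(d)
        used_tr <- rep(FALSE, length(elig))
        repeat {
          d_ok <- d
          d_ok[used_tr, ] <- Inf
          if (any(assigned_sp)) d_ok[, assigned_sp] <- Inf
          m <- which.min(d_ok)
          if (!length(m) || d_ok[m] > params$max_link_px) break
          i <- (m - 1L) %% nrow(d_ok) + 1L
          j <- (m - 1L) %/% nrow(d_ok) + 1L
          tr <- elig[i]
          rows[[length(rows) + 1]] <- data.frame(
            track_id = active$track_id[tr], frame = t,
            row = sp$row[j], col = sp$col[j], intensity = sp$intensity[j])
          active$row[tr] <- sp$row[j]; active$col[tr] <- sp$col[j]
          active$last_frame[tr] <- t
          used_tr[i] <- TRUE; assigned_sp[j] <- TRUE
          if (all(used_tr) || all(assigned_sp)) break
        }
      }
    }
    if (n_sp > 0 && any(!assigned_sp)) {
      for (j in which(!assigned_sp)) {
        next_id <- next_id + 1L
        rows[[length(rows) + 1]] <- data.frame(
          track_id = next_id, frame = t, row = sp$row[j], col = sp$col[j],
          intensity = sp$intensity[j])
        active <- rbind(active, data.frame(track_id = next_id, row = sp$row[j],
                                           col = sp$col[j], last_frame = t))
      }
    }
    active <- active[t - active$last_frame <= params$max_gap_frames, , drop = FALSE]
  }
  if (!length(rows)) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      row = numeric(0), col = numeric(0), intensity = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$track_id, out$frame), , drop = FALSE]
}

# labels of the mitochondria whose pixels lie within `rad` of (r0, c0)
.adjacent_labels <- function(labels, r0, c0, rad) {
  rs <- max(1L, floor(r0 - rad)):min(nrow(labels), ceiling(r0 + rad))
  cs <- max(1L, floor(c0 - rad)):min(ncol(labels), ceiling(c0 + rad))
  win <- labels[rs, cs, drop = FALSE]
  if (!any(win > 0L)) return(data.frame(label = integer(0), dist = numeric(0)))
  d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
  sel <- win > 0L & d2 <= rad^2
  if (!any(sel)) return(data.frame(label = integer(0), dist = numeric(0)))
  labs <- win[sel]; dd <- sqrt(d2[sel])
  agg <- tapply(dd, labs, min)
  data.frame(label = as.integer(names(agg)), dist = as.numeric(agg))
}

#' Extract tethering events from tracks and mitochondria label maps
#'
#' A tethering event opens when a track's focus lies within
#' `adjacency_radius_px` of two or more distinct mitochondria, and closes
#' at the last frame where that holds. The outcome is `fused` when the two
#' nearest partners map onto one persisting merged object in the
#' `fusion_confirm_frames` frames after the event, `separated` when they
#' remain distinct, and `censored` when the event reaches the end of the
#' stack (or there is no room to confirm). Only events strictly longer than
#' `min_event_s` are returned.
#'
#' @param tracks data.frame from [link_tracks()].
#' @param label_maps list of integer label matrices, one per frame,
#'   synchronized with the tracks.
#' @param params a [tracking_params()].
#' @return data.frame: event_id, track_id, start_frame, end_frame (1-based),
#'   duration_s, outcome, partner_a, partner_b.
#' @export
extract_events <- function(tracks, label_maps, params = tracking_params()) {
  n_frames <- length(label_maps)
  if (nrow(tracks) && max(tracks$frame) > n_frames) {
    stop("tracks reference more frames than label maps provided")
  }
  events <- list()
  for (tr in split(tracks, tracks$track_id)) {
    adj <- lapply(seq_len(nrow(tr)), function(i) {
      .adjacent_labels(label_maps[[tr$frame[i]]], tr$row[i], tr$col[i],
                       params$adjacency_radius_px)
    })
    teth <- vapply(adj, function(a) nrow(a) >= 2, logical(1))
    if (!any(teth)) next
    f_teth <- tr$frame[teth]
    idx_teth <- which(teth)
    grp <- cumsum(c(1, diff(f_teth) > params$max_gap_frames + 1L))
    for (g in unique(grp)) {
      ii <- idx_teth[grp == g]
      start <- tr$frame[ii[1]]; end <- tr$frame[ii[length(ii)]]
      duration <- (end - start) * params$dt_s
      a_end <- adj[[ii[length(ii)]]]
      a_end <- a_end[order(a_end$dist), ]
      partners <- a_end$label[1:2]
      confirm <- (end + 1L):(end + params$fusion_confirm_frames)
      outcome <- if (end >= n_frames || any(confirm > n_frames)) {
        "censored"
      } else {
        p1 <- which(label_maps[[end]] == partners[1])
        p2 <- which(label_maps[[end]] == partners[2])
        fused <- TRUE
        for (cf in confirm) {
          lab <- label_maps[[cf]]
          m1 <- lab[p1]; m1 <- m1[m1 > 0L]
          m2 <- lab[p2]; m2 <- m2[m2 > 0L]
          if (!length(m1) || !length(m2)) { fused <- FALSE; break }
          top1 <- as.integer(names(which.max(table(m1))))
          top2 <- as.integer(names(which.max(table(m2))))
          if (top1 != top2) { fused <- FALSE; break }
        }
        if (fused) "fused" else "separated"
      }
      events[[length(events) + 1]] <- data.frame(
        track_id = tr$track_id[1], start_frame = start, end_frame = end,
        duration_s = duration, outcome = outcome,
        partner_a = partners[1], partner_b = partners[2])
    }
  }
  if (!length(events)) {
    return(data.frame(event_id = integer(0), track_id = integer(0),
                      start_frame = integer(0), end_frame = integer(0),
                      duration_s = numeric(0), outcome = character(0),
                      partner_a = integer(0), partner_b = integer(0)))
  }
  out <- do.call(rbind, events)
  out <- out[out$duration_s > params$min_event_s, , drop = FALSE]
  if (nrow(out)) out <- cbind(event_id = seq_len(nrow(out)), out)
  else out <- cbind(event_id = integer(0), out)
  rownames(out) <- NULL
  out
}

#' Tethering-duration statistics, optionally compared between conditions
#'
#' Mean and SEM of event durations per condition (censored events are
#' excluded from duration statistics), counts of fruitful (fused) versus
#' unfruitful events, and, for exactly two conditions, the ratio of mean
#' durations (second/first) with a Welch t-test p-value (delegated to
#' [stats::t.test()]).
#'
#' @param events data.frame from [extract_events()].
#' @param condition character vector, one entry per event (recycled if a
#'   single value); order of first appearance fixes which condition is the
#'   ratio denominator.
#' @return list with `summary` (per-condition data.frame), and for two
#'   conditions `ratio` and `p_value`.
#' @export
tether_stats <- function(events, condition = "all") {
  if (nrow(events) == 0) stop("no events to summarize")
  condition <- rep_len(as.character(condition), nrow(events))
  conds <- unique(condition)
  summ <- do.call(rbind, lapply(conds, function(cd) {
    ev <- events[condition == cd, , drop = FALSE]
    if (nrow(ev) == 0) stop("condition without events: ", cd)
    dur <- ev$duration_s[ev$outcome != "censored"]
    data.frame(condition = cd, n_events = nrow(ev),
               n_censored = sum(ev$outcome == "censored"),
               mean_duration_s = mean(dur), sem_duration_s = .sem(dur),
               fruitful = sum(ev$outcome == "fused"),
               unfruitful = sum(ev$outcome == "separated"))
  }))
  out <- list(summary = summ)
  if (length(conds) == 2) {
    d1 <- events$duration_s[condition == conds[1] &
                              events$outcome != "censored"]
    d2 <- events$duration_s[condition == conds[2] &
                              events$outcome != "censored"]
    out$ratio <- mean(d2) / mean(d1)
    out$p_value <- tryCatch(stats::t.test(d2, d1)$p.value,
                            error = function(e) NA_real_)
  }
  out
}

#' Run the tethering pipeline on a generated or loaded time-lapse
#'
#' Segments each mitochondria frame (reusing the label map across frames
#' that are identical to the previous one), detects and links foci, and
#' extracts tethering events.
#'
#' @param foci,mito lists of frame matrices (foci and mitochondria channel).
#' @param params a [tracking_params()].
#' @param seg_params a [segmentation_params()] for the mitochondria channel;
#'   the default skips background subtraction (synthetic stacks are flat).
#' @return data.frame of events from [extract_events()].
#' @export
track_tethering <- function(foci, mito, params = tracking_params(),
                            seg_params = segmentation_params(
                              threshold_method = "fixed", fixed_threshold = 0.3)) {
  stopifnot(length(foci) == length(mito))
  label_maps <- vector("list", length(mito))
  for (t in seq_along(mito)) {
    if (t > 1 && identical(mito[[t]], mito[[t - 1]])) {
      label_maps[[t]] <- label_maps[[t - 1]]
    } else {
      label_maps[[t]] <- segment_image(mito[[t]], seg_params)
    }
  }
  spots <- lapply(foci, detect_foci, params = params)
  tracks <- link_tracks(spots, params)
  extract_events(tracks, label_maps, params)
}
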