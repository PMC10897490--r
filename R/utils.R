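# Internal helpers: seeded evaluation, raster rendering primitives,
# separable Gaussian smoothing, and connected-component labeling.

#' Evaluate code under a temporary RNG state
#'
#' Sets the RNG to `seed`, runs `code`, and restores the caller's RNG state,
#' so generators are reproducible without disturbing the session.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Stable per-module seed stream derived from one global seed. Kept below
# 2^31 so it is always a valid integer seed.
.derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) %% 65011 + 1) * 32749 + h * 97) %% 2147483629L
}

# ---- raster rendering -------------------------------------------------------

.blank_image <- function(size) matrix(0, nrow = size[1], ncol = size[2])

# Pixels (as linear indices) within `radius` of point (r0, c0).
.disc_pixels <- function(dim, r0, c0, radius) {
  rr <- max(1L, floor(r0 - radius)):min(dim[1], ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(dim[2], ceiling(c0 + radius))
  if (!length(rr) || !length(cc)) return(integer(0))
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - r0)^2 + (g$c - c0)^2 <= radius^2
  (g$c[keep] - 1L) * dim[1] + g$r[keep]
}

# Pixels within width/2 of the open polyline `pts` (n x 2 matrix, (row, col)).
.tube_pixels <- function(dim, pts, width) {
  rad <- width / 2
  rr <- max(1L, floor(min(pts[, 1]) - rad)):min(dim[1], ceiling(max(pts[, 1]) + rad))
  cc <- max(1L, floor(min(pts[, 2]) - rad)):min(dim[2], ceiling(max(pts[, 2]) + rad))
  if (!length(rr) || !length(cc)) return(integer(0))
  g <- expand.grid(r = rr, c = cc)
  d2 <- rep(Inf, nrow(g))
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      dd <- (g$r - a[1])^2 + (g$c - a[2])^2
    } else {
      t <- pmin(1, pmax(0, ((g$r - a[1]) * ab[1] + (g$c - a[2]) * ab[2]) / len2))
      dd <- (g$r - (a[1] + t * ab[1]))^2 + (g$c - (a[2] + t * ab[2]))^2
    }
    d2 <- pmin(d2, dd)
  }
  keep <- d2 <= rad^2
  (g$c[keep] - 1L) * dim[1] + g$r[keep]
}

# Quadratic Bezier sampled at n points; p0, p1 endpoints, ctrl control point.
.bezier_points <- function(p0, ctrl, p1, n) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * ctrl[1] + t^2 * p1[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * ctrl[2] + t^2 * p1[2])
}

# Minimum distance between two segments (p1,p2) and (q1,q2), each (row, col).
.seg_dist <- function(p1, p2, q1, q2) {
  pt_seg <- function(p, a, b) {
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) return(sqrt(sum((p - a)^2)))
    t <- min(1, max(0, sum((p - a) * ab) / len2))
    sqrt(sum((p - (a + t * ab))^2))
  }
  orient <- function(a, b, c) {
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  }
  crosses <- orient(p1, p2, q1) * orient(p1, p2, q2) < 0 &&
    orient(q1, q2, p1) * orient(q1, q2, p2) < 0
  if (crosses) return(0)
  min(pt_seg(p1, q1, q2), pt_seg(p2, q1, q2), pt_seg(q1, p1, p2), pt_seg(q2, p1, p2))
}

# ---- shifted matrices and smoothing ----------------------------------------

# Shift matrix by (dr, dc), padding with `fill`.
.shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Separable Gaussian smoothing as two banded-matrix products (BLAS-fast);
# band matrices are row-normalized (exact truncated-kernel edge handling)
# and cached per (size, sigma).
.smooth_cache <- new.env(parent = emptyenv())

.gauss_band <- function(n, sigma) {
  key <- paste(n, signif(sigma, 8), sep = "_")
  B <- .smooth_cache[[key]]
  if (is.null(B)) {
    rad <- max(1L, ceiling(2.5 * sigma))
    B <- matrix(0, n, n)
    for (off in -rad:rad) {
      w <- stats::dnorm(off, sd = sigma)
      i <- seq_len(n)
      j <- i + off
      ok <- j >= 1 & j <= n
      B[cbind(i[ok], j[ok])] <- w
    }
    B <- B / rowSums(B)
    .smooth_cache[[key]] <- B
  }
  B
}

.gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  .gauss_band(nrow(m), sigma) %*% m %*% t(.gauss_band(ncol(m), sigma))
}

# Indices (into m) of candidate pixels that are >= all 8 neighbors.
# Candidates on the outermost pixel ring are dropped.
.local_max_at <- function(m, idx) {
  nr <- nrow(m)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  interior <- rr > 1L & rr < nr & cc > 1L & cc < ncol(m)
  idx <- idx[interior]
  if (!length(idx)) return(integer(0))
  v <- m[idx]
  ok <- rep(TRUE, length(idx))
  for (off in c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)) {
    ok <- ok & v >= m[idx + off]
  }
  idx[ok]
}

# ---- connected components ---------------------------------------------------

#' Label connected components of a binary image
#'
#' 4-connected labeling is delegated to [EBImage::bwlabel()]; 8-connectivity
#' additionally merges labels that touch diagonally.
#'
#' @param bw logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of labels, 0 = background, labels contiguous from 1.
#' @export
label_components <- function(bw, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  bw <- matrix(as.numeric(bw > 0), nrow(bw), ncol(bw))
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n == 0L) return(lab)
  if (connectivity == 8) {
    pairs <- NULL
    for (d in list(c(1L, 1L), c(1L, -1L))) {
      sh <- .shift_mat(lab, d[1], d[2], fill = 0L)
      sel <- lab > 0L & sh > 0L & lab != sh
      if (any(sel)) pairs <- rbind(pairs, cbind(lab[sel], sh[sel]))
    }
    if (!is.null(pairs)) {
      g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
      g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
      memb <- igraph::components(g)$membership
      lab[lab > 0L] <- as.integer(memb[lab[lab > 0L]])
      n <- max(lab)
    }
  }
  # contiguous relabeling ordered by first pixel occurrence
  first <- match(seq_len(n), lab[lab > 0L])
  ord <- order(first)
  remap <- integer(n)
  remap[ord] <- seq_len(n)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# standard error of the mean; 0 for a single observation
.sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0)
  stats::sd(x) / sqrt(length(x))
}
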