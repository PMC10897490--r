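# Independent brute-force oracles used to check the pipeline's measurements.
# These deliberately avoid the package's own code paths.

# Second-central-moment ellipse axis ratio from raw pixel coordinates,
# computed with explicit sums (no eigen shortcuts shared with the package).
oracle_moment_ar <- function(mask) {
  idx <- which(mask > 0)
  r <- (idx - 1) %% nrow(mask) + 1
  c <- (idx - 1) %/% nrow(mask) + 1
  n <- length(r)
  mr <- sum(r) / n; mc <- sum(c) / n
  uxx <- sum((r - mr)^2) / n
  uyy <- sum((c - mc)^2) / n
  uxy <- sum((r - mr) * (c - mc)) / n
  common <- sqrt((uxx - uyy)^2 + 4 * uxy^2)
  l1 <- (uxx + uyy + common) / 2
  l2 <- (uxx + uyy - common) / 2
  sqrt(l1 / l2)
}

# Render a filled rectangle of given side lengths rotated by theta (deg),
# centered in an image of side `n`: pixel centers inside the rectangle.
render_rect <- function(len, wid, theta_deg, n = 160) {
  th <- theta_deg * pi / 180
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  x <- g$r - (n + 1) / 2; y <- g$c - (n + 1) / 2
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  m <- matrix(0, n, n)
  m[abs(u) <= len / 2 & abs(v) <= wid / 2] <- 1
  m
}

# Brute-force grayscale morphological opening with a disc structuring
# element (erosion then dilation, straight window loops). Small inputs only.
oracle_opening <- function(img, radius) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  nr <- nrow(img); nc <- ncol(img)
  stage <- function(x, f, pad) {
    out <- matrix(pad, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      rr <- r + offs$dr; cc <- c + offs$dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      out[r, c] <- f(x[cbind(rr[ok], cc[ok])])
    }
    out
  }
  stage(stage(img, min, Inf), max, -Inf)
}

# Exhaustive-assignment linking oracle for two spots per frame: tracks keep
# identity by choosing, per frame, the pairing with the smaller total
# displacement.
oracle_link_two <- function(spots) {
  pos <- list(a = unlist(spots[[1]][1, c("row", "col")]),
              b = unlist(spots[[1]][2, c("row", "col")]))
  ids <- list(a = 1L, b = 2L)
  paths <- list(a = list(pos$a), b = list(pos$b))
  for (t in 2:length(spots)) {
    p1 <- unlist(spots[[t]][1, c("row", "col")])
    p2 <- unlist(spots[[t]][2, c("row", "col")])
    keep <- sum((pos$a - p1)^2) + sum((pos$b - p2)^2)
    swap <- sum((pos$a - p2)^2) + sum((pos$b - p1)^2)
    if (keep <= swap) { pos$a <- p1; pos$b <- p2 }
    else { pos$a <- p2; pos$b <- p1 }
    paths$a[[t]] <- pos$a; paths$b[[t]] <- pos$b
  }
  paths
}

# Run-extraction oracle on a sampled distance sequence: explicit scan for
# maximal runs of (distance <= threshold, constant nearest id).
oracle_runs <- function(dist, id, thr = 60) {
  runs <- list()
  open <- FALSE
  for (i in seq_along(dist)) {
    inc <- dist[i] <= thr
    if (inc && !open) { start <- i; cur <- id[i]; open <- TRUE }
    else if (inc && open && id[i] != cur) {
      runs[[length(runs) + 1]] <- c(start, i - 1); start <- i; cur <- id[i]
    } else if (!inc && open) {
      runs[[length(runs) + 1]] <- c(start, i - 1); open <- FALSE
    }
  }
  if (open) runs[[length(runs) + 1]] <- c(start, length(dist))
  runs
}

# Interval-union oracle on a line (sorted sweep over explicit endpoints).
oracle_union_length <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0; cs <- starts[1]; ce <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ce) ce <- max(ce, ends[i])
    else { tot <- tot + ce - cs; cs <- starts[i]; ce <- ends[i] }
  }
  tot + ce - cs
}

# Point-to-polygon boundary distance by dense boundary sampling.
oracle_poly_dist <- function(p, poly, n_per_edge = 200) {
  d <- Inf
  for (i in seq_len(nrow(poly))) {
    a <- poly[i, ]; b <- poly[if (i == nrow(poly)) 1 else i + 1, ]
    t <- seq(0, 1, length.out = n_per_edge)
    pts <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
    d <- min(d, sqrt(min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)))
  }
  d
}
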