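# Independent reference implementations used as oracles. They recompute
# quantities by direct simulation or exhaustive search, sharing no code
# path with the package internals.

# Balanced-histogram iteration simulated literally: at every step the side
# weights are re-summed from scratch around the interval midpoint and one
# outer bin is dropped from the heavier side.
bht_reference <- function(h) {
  h <- as.numeric(h)
  h[1] <- 0
  nz <- which(h > 0) - 1L
  lo <- min(nz); hi <- max(nz)
  if (lo == hi) return(lo - 1L)
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    wl <- sum(h[(lo:mid) + 1L])
    wr <- if (mid + 1L > hi) 0 else sum(h[((mid + 1L):hi) + 1L])
    if (wl <= 0 && wr <= 0) return(mid)
    if (wr > wl) hi <- hi - 1L else lo <- lo + 1L
  }
  (lo + hi) %/% 2L
}

# Exhaustive minimum enclosing circle: the optimum is supported by two or
# three points, so try every pair (as a diameter) and every triple (as a
# circumcircle, found by solving the perpendicular-bisector system) and
# keep the smallest circle that covers all points.
mec_brute_force <- function(pts) {
  pts <- unname(unique(pts[, 1:2, drop = FALSE]))
  colnames(pts) <- NULL
  if (nrow(pts) > 3L) {
    # interior points can never support the optimum; dropping them keeps
    # the exhaustive pair/triple search tractable without changing it
    pts <- pts[chull(pts), , drop = FALSE]
  }
  n <- nrow(pts)
  if (n == 1L) return(list(center = pts[1, ], radius = 0))
  covers <- function(ctr, r) {
    all(sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2) <= r + 1e-9)
  }
  best <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ctr <- (pts[i, ] + pts[j, ]) / 2
    r <- sqrt(sum((pts[i, ] - pts[j, ])^2)) / 2
    if ((is.null(best) || r < best$radius - 1e-12) && covers(ctr, r))
      best <- list(center = ctr, radius = r)
  }
  if (n >= 3L) for (i in seq_len(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; cpt <- pts[k, ]
    A <- rbind(2 * (b - a), 2 * (cpt - a))
    if (abs(det(A)) < 1e-12) next
    rhs <- c(sum(b^2) - sum(a^2), sum(cpt^2) - sum(a^2))
    ctr <- solve(A, rhs)
    r <- sqrt(sum((a - ctr)^2))
    if ((is.null(best) || r < best$radius - 1e-12) && covers(ctr, r))
      best <- list(center = ctr, radius = r)
  }
  best
}

# total variation (anisotropic sum of finite-difference gradient magnitudes)
total_variation <- function(img) {
  g1 <- img[-1, ] - img[-nrow(img), ]
  g2 <- img[, -1] - img[, -ncol(img)]
  sum(abs(g1)) + sum(abs(g2))
}

# rasterize a disk of radius r centred in its own little image
raster_disk <- function(r, pad = 3L) {
  n <- 2L * r + 2L * pad
  ctr <- n / 2
  m <- matrix(0L, n, n)
  m[(row(m) - ctr)^2 + (col(m) - ctr)^2 <= r^2] <- 1L
  m
}

pix_of <- function(mask) {
  idx <- which(mask > 0)
  cbind(((idx - 1L) %% nrow(mask)) + 1L, ((idx - 1L) %/% nrow(mask)) + 1L)
}
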