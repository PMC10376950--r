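#' Circularity of an object
#'
#' `4 * pi * area / perimeter^2`: 1 for an ideal circle, < 1 the less
#' circular the object. On a raster the perimeter is an estimate (see
#' [crofton_perimeter()]), so tiny components may slightly overshoot 1.
#' A single-pixel object (no measurable boundary length) is defined as
#' maximally compact, circularity 1.
#'
#' @param area object area (pixel count, or continuum area).
#' @param perimeter boundary length in px.
#' @return circularity value.
#' @export
circularity <- function(area, perimeter) {
  stopifnot(length(area) == length(perimeter))
  out <- ifelse(perimeter <= 0, 1, 4 * pi * area / perimeter^2)
  out[area == 1] <- 1
  out
}

#' Crofton perimeter estimate of a binary mask
#'
#' Weighted boundary-crossing estimator based on the Cauchy-Crofton formula
#' with four test directions: each 2x2 pixel configuration along the object
#' boundary contributes a fixed weight to the total length. Unlike a raw
#' chain-code count this estimator is asymptotically unbiased for smooth
#' shapes, so the circularity of rasterized disks converges to 1 as the
#' radius grows.
#'
#' @param mask logical or 0/1 matrix; `> 0` is foreground.
#' @return estimated total boundary length in px of all foreground objects.
#' @export
crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) * 1L
  h <- nrow(m); w <- ncol(m)
  zr <- matrix(0L, 1L, w)
  zc <- matrix(0L, h, 1L)
  left  <- cbind(zc, m[, -w, drop = FALSE])
  up    <- rbind(zr, m[-h, , drop = FALSE])
  upleft <- rbind(zr, cbind(0L, m[-h, -w, drop = FALSE]))
  code <- m + 4L * left + 2L * up + 8L * upleft
  cnt <- tabulate(code + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2),
             0, pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
             pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
             pi / 4, pi / 2, 0, 0)
  sum(cnt * coefs)
}

# corner points (x, y) of the pixel squares of a pixel set given as a
# two-column (row, col) matrix; pixel (r, c) occupies [c-.5, c+.5] x [r-.5, r+.5]
.pixel_corners <- function(pix) {
  x <- pix[, 2]; y <- pix[, 1]
  pts <- cbind(x = c(x - 0.5, x + 0.5, x - 0.5, x + 0.5),
               y = c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
  unique(pts)
}

#' Minimum-area (rotated) bounding rectangle
#'
#' Rotating-calipers search over the convex hull: the minimum-area enclosing
#' rectangle has one side collinear with a hull edge. Operates on arbitrary
#' 2-D points; component metrics use the corner points of the pixel squares
#' so that a 1-pixel-thick object has width 1, not 0.
#'
#' @param pts two-column matrix of (x, y) points.
#' @return list with `width` (shorter side), `height` (longer side), `area`.
#' @export
min_area_rect <- function(pts) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  n <- nrow(pts)
  if (n == 1L) return(list(width = 0, height = 0, area = 0))
  hi <- chull(pts)
  hull <- pts[hi, , drop = FALSE]
  m <- nrow(hull)
  if (m == 2L) {
    len <- sqrt(sum((hull[1, ] - hull[2, ])^2))
    return(list(width = 0, height = len, area = 0))
  }
  best <- NULL
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len
    v <- c(-u[2], u[1])
    pu <- hull %*% u
    pv <- hull %*% v
    e1 <- max(pu) - min(pu)
    e2 <- max(pv) - min(pv)
    a <- e1 * e2
    if (is.null(best) || a < best$area - 1e-12)
      best <- list(width = min(e1, e2), height = max(e1, e2), area = a)
  }
  best
}

#' Bounding-box ratio of a pixel set
#'
#' Ratio of the shorter to the longer side of the minimum-area rotated
#' rectangle enclosing the pixel squares; 1 for a square footprint, small
#' for elongated objects. A single pixel gives 1 by convention; a
#' degenerate zero-height rectangle gives 0.
#'
#' @param pix two-column (row, col) matrix of pixel coordinates.
#' @return ratio in `(0, 1]` (0 only in the degenerate collinear case).
#' @export
bbox_ratio <- function(pix) {
  if (nrow(pix) == 1L) return(1)
  r <- min_area_rect(.pixel_corners(pix))
  if (r$height <= 0) return(0)
  r$width / r$height
}

#' Minimum enclosing circle
#'
#' Smallest circle containing all the points, computed by Welzl's
#' move-to-front recursion on the convex hull (the optimum is supported by
#' at most three hull points).
#'
#' @param pts two-column matrix of (x, y) points.
#' @return list with `center` (x, y) and `radius`.
#' @export
min_enclosing_circle <- function(pts) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  n <- nrow(pts)
  if (n == 1L) return(list(center = as.numeric(pts[1, ]), radius = 0))
  if (n > 3L) {
    hi <- chull(pts)
    pts <- pts[hi, , drop = FALSE]
    n <- nrow(pts)
  }
  circ <- .welzl(pts, matrix(numeric(0), 0, 2))
  list(center = unname(circ[1:2]), radius = unname(circ[3]))
}

.circle_two <- function(a, b) {
  c((a + b) / 2, sqrt(sum((a - b)^2)) / 2)
}

.circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)  # collinear
  ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
           (sum(c^2)) * (a[2] - b[2])) / d
  uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
           (sum(c^2)) * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  c(ctr, sqrt(sum((a - ctr)^2)))
}

.circle_contains <- function(circ, p, tol = 1e-9) {
  sqrt(sum((p - circ[1:2])^2)) <= circ[3] + tol
}

.trivial_circle <- function(R) {
  k <- nrow(R)
  if (k == 0L) return(c(0, 0, -1))
  if (k == 1L) return(c(R[1, ], 0))
  if (k == 2L) return(.circle_two(R[1, ], R[2, ]))
  # three support points: try pairs first (one may be interior)
  for (i in 1:2) for (j in (i + 1):3) {
    cc <- .circle_two(R[i, ], R[j, ])
    other <- setdiff(1:3, c(i, j))
    if (.circle_contains(cc, R[other, ])) return(cc)
  }
  cc <- .circumcircle(R[1, ], R[2, ], R[3, ])
  if (is.null(cc)) {  # collinear support: span of extremes
    d12 <- sum((R[1, ] - R[2, ])^2)
    d13 <- sum((R[1, ] - R[3, ])^2)
    d23 <- sum((R[2, ] - R[3, ])^2)
    m <- which.max(c(d12, d13, d23))
    pr <- list(c(1, 2), c(1, 3), c(2, 3))[[m]]
    cc <- .circle_two(R[pr[1], ], R[pr[2], ])
  }
  cc
}

.welzl <- function(P, R) {
  if (nrow(P) == 0L || nrow(R) == 3L) return(.trivial_circle(R))
  p <- P[nrow(P), ]
  D <- .welzl(P[-nrow(P), , drop = FALSE], R)
  if (D[3] >= 0 && .circle_contains(D, p)) return(D)
  .welzl(P[-nrow(P), , drop = FALSE], rbind(R, p))
}

#' Enclosed-circle ratio of a pixel set
#'
#' Ratio of the object area to the area of the minimum circle enclosing the
#' pixel squares. 1 for a perfect circle and strictly below 1 otherwise
#' (the enclosing circle covers every pixel square, so its area bounds the
#' object area from above).
#'
#' @param pix two-column (row, col) matrix of pixel coordinates.
#' @return ratio in `(0, 1]`.
#' @export
enclosed_circle_ratio <- function(pix) {
  mec <- min_enclosing_circle(.pixel_corners(pix))
  e <- pi * mec$radius^2
  if (e <= 0) return(1)
  nrow(pix) / e
}

#' Shape record of one connected component
#'
#' Computes the roundness metrics used by both the artery and the bronchus
#' screens: pixel area, Crofton perimeter, circularity, minimum-rotated-
#' bounding-box side ratio, enclosed-circle area ratio, and the sub-pixel
#' centroid.
#'
#' @param pix two-column (row, col) matrix of the component's pixels.
#' @param label integer component label.
#' @return object of class `"ba_component"`: a list with `label`, `pixels`,
#'   `area`, `perimeter`, `circularity`, `bbox_ratio`, `ec_ratio`,
#'   `centroid` (x, y).
#' @export
component_record <- function(pix, label = 1L) {
  stopifnot(is.matrix(pix), ncol(pix) == 2, nrow(pix) >= 1)
  area <- nrow(pix)
  rr <- range(pix[, 1]); cr <- range(pix[, 2])
  m <- matrix(FALSE, rr[2] - rr[1] + 1L, cr[2] - cr[1] + 1L)
  m[cbind(pix[, 1] - rr[1] + 1L, pix[, 2] - cr[1] + 1L)] <- TRUE
  per <- crofton_perimeter(m)
  structure(list(
    label = as.integer(label),
    pixels = pix,
    area = area,
    perimeter = per,
    circularity = circularity(area, per),
    bbox_ratio = bbox_ratio(pix),
    ec_ratio = enclosed_circle_ratio(pix),
    centroid = c(x = mean(pix[, 2]), y = mean(pix[, 1]))
  ), class = "ba_component")
}

#' @export
print.ba_component <- function(x, ...) {
  cat(sprintf(
    "component %d: A=%d P=%.2f Cr=%.3f BB=%.3f EC=%.3f centroid=(%.1f, %.1f)\n",
    x$label, x$area, x$perimeter, x$circularity, x$bbox_ratio, x$ec_ratio,
    x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' All component records of a labelled image
#'
#' @param lab integer label matrix from [label_components()].
#' @return list of [component_record()] objects, ordered by label.
#' @export
component_records <- function(lab) {
  px <- .pixels_by_label(lab)
  h <- nrow(lab)
  lapply(names(px), function(k) {
    idx <- px[[k]]
    pix <- cbind(row = ((idx - 1L) %% h) + 1L, col = ((idx - 1L) %/% h) + 1L)
    component_record(pix, as.integer(k))
  })
}

#' Screening gates for candidate arteries and bronchi
#'
#' Threshold sets for the four-condition roundness screen. The artery gates
#' keep components with `10 <= area < 300`, circularity > 0.3, bounding-box
#' ratio > 0.4 and enclosed-circle ratio > 0.4; the bronchus gates keep
#' holes with area > 3 px, circularity > 0.5 and both shape ratios > 0.6.
#'
#' @param area_min,area_max area window: kept when `area_min <= A < area_max`.
#' @param cr_min,bb_min,ec_min strict lower bounds on circularity,
#'   bounding-box ratio and enclosed-circle ratio.
#' @return named list of thresholds.
#' @export
condition_gates <- function(area_min, area_max, cr_min, bb_min, ec_min) {
  list(area_min = area_min, area_max = area_max,
       cr_min = cr_min, bb_min = bb_min, ec_min = ec_min)
}

#' @rdname condition_gates
#' @export
artery_gates <- function() condition_gates(10, 300, 0.3, 0.4, 0.4)

#' @rdname condition_gates
#' @export
bronchus_gates <- function() condition_gates(4, Inf, 0.5, 0.6, 0.6)

#' Four-condition roundness screen
#'
#' A component is kept only when all four conditions hold: area inside the
#' window (`area_min <= A < area_max`) and circularity, bounding-box ratio
#' and enclosed-circle ratio each strictly above their thresholds.
#'
#' @param component a [component_record()].
#' @param gates a [condition_gates()] list.
#' @return `TRUE` if the component passes all four conditions.
#' @export
passes_conditions <- function(component, gates) {
  (component$area >= gates$area_min && component$area < gates$area_max) &&
    component$circularity > gates$cr_min &&
    component$bbox_ratio > gates$bb_min &&
    component$ec_ratio > gates$ec_min
}
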