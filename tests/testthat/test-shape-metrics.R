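test_that("circularity matches continuum closed forms", {
  r <- 7.3
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  s <- 4
  expect_equal(circularity(s^2, 4 * s), pi / 4)
  expect_equal(circularity(10, 22), 40 * pi / 484)
  expect_equal(circularity(1, 0), 1)   # single pixel: maximally compact
})

test_that("circularity of rasterized disks rises monotonically to 1", {
  crs <- vapply(c(5, 10, 20, 40), function(r) {
    d <- raster_disk(r)
    circularity(sum(d), crofton_perimeter(d))
  }, numeric(1))
  expect_true(all(diff(crs) > 0))
  expect_lt(abs(crs[1] - 1), 0.15)
  expect_lt(abs(crs[4] - 1), 0.05)
  expect_true(all(crs <= 1.1))
})

test_that("bounding-box ratio handles squares, rectangles and rotation", {
  sq <- as.matrix(expand.grid(3:7, 3:7))
  expect_equal(bbox_ratio(sq), 1)

  rect <- as.matrix(expand.grid(1:2, 1:5))
  expect_equal(bbox_ratio(rect), 0.4)

  # rectangles of aspect 0.4 rasterized after a 30 degree rotation: the
  # ratio approaches 0.4 as the object grows; at ~10 px the pixel squares
  # inflate the short side by a full pixel (bias towards 1 for tiny blobs)
  rot_rect <- function(half_w, half_h, ext) {
    th <- 30 * pi / 180
    g <- as.matrix(expand.grid(x = -ext:ext, y = -ext:ext))
    xr <- g[, 1] * cos(th) + g[, 2] * sin(th)
    yr <- -g[, 1] * sin(th) + g[, 2] * cos(th)
    inside <- abs(xr) <= half_w & abs(yr) <= half_h
    unname(cbind(g[inside, 2], g[inside, 1]) + ext + 1L)
  }
  expect_lt(abs(bbox_ratio(rot_rect(5, 2, 8)) - 0.4), 0.15)
  expect_lt(abs(bbox_ratio(rot_rect(10, 4, 10)) - 0.4), 0.1)
  expect_lt(abs(bbox_ratio(rot_rect(2.5, 1, 5)) - 0.4), 0.25)

  expect_equal(bbox_ratio(matrix(c(4, 9), 1)), 1)  # single pixel convention
})

test_that("enclosed-circle ratio matches closed forms and the brute-force oracle", {
  # square of side s: s^2 / (pi * (s * sqrt(2) / 2)^2) = 2 / pi
  sq <- as.matrix(expand.grid(1:6, 1:6))
  colnames(sq) <- NULL
  expect_equal(enclosed_circle_ratio(sq), 2 / pi, tolerance = 1e-10)

  d <- raster_disk(10)
  expect_gt(enclosed_circle_ratio(pix_of(d)), 0.85)

  # random small components: Welzl equals the exhaustive pair/triple search
  set.seed(99)
  for (i in 1:30) {
    npx <- sample(1:30, 1)
    pix <- unique(cbind(sample(1:12, npx, TRUE), sample(1:12, npx, TRUE)))
    pts <- bapair:::.pixel_corners(pix)
    got <- min_enclosing_circle(pts)
    ref <- mec_brute_force(pts)
    expect_equal(got$radius, ref$radius, tolerance = 1e-9)
  }
})

test_that("shape ratios are invariant under translation and rotation", {
  set.seed(7)
  pix <- unique(cbind(sample(1:15, 40, TRUE), sample(1:15, 40, TRUE)))
  ec0 <- enclosed_circle_ratio(pix)
  bb0 <- bbox_ratio(pix)

  shift <- pix + matrix(rep(c(100L, 37L), each = nrow(pix)), ncol = 2)
  expect_equal(enclosed_circle_ratio(shift), ec0)
  expect_equal(bbox_ratio(shift), bb0)

  rot90 <- cbind(pix[, 2], 100L - pix[, 1])   # 90 degree rotation (exact)
  expect_equal(enclosed_circle_ratio(rot90), ec0)
  expect_equal(bbox_ratio(rot90), bb0)
})

test_that("the four-condition screen is a strict conjunction", {
  gates <- artery_gates()
  mk <- function(area, cr, bb, ec) {
    list(area = area, circularity = cr, bbox_ratio = bb, ec_ratio = ec)
  }
  expect_true(passes_conditions(mk(50, 0.9, 0.95, 0.9), gates))
  expect_false(passes_conditions(mk(500, 0.99, 1, 1), gates))   # too large
  expect_false(passes_conditions(mk(9, 0.99, 1, 1), gates))     # too small
  expect_false(passes_conditions(mk(50, 0.3, 0.95, 0.9), gates))  # Cr strict
  expect_false(passes_conditions(mk(50, 0.9, 0.4, 0.9), gates))   # BB strict
  expect_false(passes_conditions(mk(50, 0.9, 0.95, 0.4), gates))  # EC strict
  expect_true(passes_conditions(mk(300, 0.9, 0.95, 0.9),
                                condition_gates(10, 301, 0.3, 0.4, 0.4)))
})

test_that("component records carry consistent metrics", {
  d <- raster_disk(6)
  lab <- label_components(d)
  recs <- component_records(lab)
  expect_length(recs, 1L)
  r <- recs[[1]]
  expect_equal(r$area, sum(d))
  expect_equal(r$perimeter, crofton_perimeter(d))
  ctr <- (nrow(d)) / 2
  expect_lt(abs(r$centroid["x"] - ctr), 0.6)
  expect_lt(abs(r$centroid["y"] - ctr), 0.6)

  # two diagonal pixels are one component under 8-connectivity
  m <- matrix(0, 4, 4); m[2, 2] <- 1; m[3, 3] <- 1
  expect_equal(max(label_components(m)), 1L)
  # labels are assigned in row-major first-appearance order
  m2 <- matrix(0, 5, 5); m2[1, 4] <- 1; m2[3, 1] <- 1
  lab2 <- label_components(m2)
  expect_equal(lab2[1, 4], 1L)
  expect_equal(lab2[3, 1], 2L)
})
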