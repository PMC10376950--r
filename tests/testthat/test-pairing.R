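# Build a synthetic updated-clean scene: an artery disk touching a
# bronchus ring, plus optional isolated structures. Returns the pieces the
# pairing stage consumes.
mk_scene <- function(with_artery = TRUE, lone_ring = TRUE, slit = FALSE) {
  size <- 200L
  img <- matrix(0, size, size)
  rr <- row(img); cc <- col(img)
  ring <- function(x, y, r_in, r_out) {
    d2 <- (rr - y)^2 + (cc - x)^2
    img[d2 <= r_out^2 & d2 > r_in^2] <<- 100
  }
  disk <- function(x, y, r, val = 225) {
    img[(rr - y)^2 + (cc - x)^2 <= r^2] <<- val
  }
  ring(60, 60, 4, 7)                    # bronchus: lumen r=4, wall to r=7
  if (with_artery) disk(73, 60, 7)      # artery tangent to the wall
  if (lone_ring) ring(140, 140, 4, 7)   # ring with no artery nearby
  if (slit) {                           # ring with a 1x8 slit lumen
    disk(60, 150, 7, val = 100)
    img[150, 53:60] <- 0
  }
  as_gray_image(img)
}

run_artery_stage <- function(img) {
  detect_potential_arteries(img)
}

test_that("only components overlapping a kept artery become host contours", {
  img <- mk_scene()
  art <- run_artery_stage(img)
  expect_length(art$kept, 1L)
  hosts <- extract_adjacent_objects(art$updated_clean, art)
  # the merged ring+artery component is kept; the lone ring is not
  expect_length(hosts, 1L)
  expect_true(any(hosts[[1]]$pixels[, 1] == 60))
  expect_gt(hosts[[1]]$area, art$kept[[1]]$area)

  # two arteries merged into one component: the component is kept once
  img2 <- mk_scene(lone_ring = FALSE)
  d2 <- (row(img2) - 60)^2 + (col(img2) - 87)^2
  img2[d2 <= 49] <- 225                 # second artery touching the first
  art2 <- run_artery_stage(img2)
  hosts2 <- extract_adjacent_objects(art2$updated_clean, art2)
  expect_length(hosts2, 1L)
})

test_that("potential bronchi are holes passing the roundness screen", {
  img <- mk_scene()
  art <- run_artery_stage(img)
  hosts <- extract_adjacent_objects(art$updated_clean, art)
  hm <- records_to_mask(hosts, dim(img))
  br <- detect_potential_bronchi(hm)
  expect_length(br$bronchi, 1L)
  b <- br$bronchi[[1]]
  expect_gt(b$area, 3)
  expect_gt(b$circularity, 0.5)
  expect_lt(abs(b$centroid["x"] - 60), 1.1)

  # a solid disk has no holes
  solid <- matrix(0, 50, 50)
  solid[(row(solid) - 25)^2 + (col(solid) - 25)^2 <= 100] <- 1
  expect_length(detect_potential_bronchi(solid)$bronchi, 0L)

  # a slit-shaped lumen fails the circularity/bounding-box conditions
  slit <- matrix(0, 40, 40)
  slit[10:30, 10:30] <- 1
  slit[20, 15:22] <- 0
  res <- detect_potential_bronchi(slit)
  expect_true(any(res$hole_mask))
  expect_length(res$bronchi, 0L)
})

test_that("bronchi pair with the nearest artery of their host contour", {
  img <- mk_scene()
  art <- run_artery_stage(img)
  hosts <- extract_adjacent_objects(art$updated_clean, art)
  hm <- records_to_mask(hosts, dim(img))
  br <- detect_potential_bronchi(hm)
  lung <- matrix(TRUE, nrow(img), ncol(img))
  pairs <- extract_ba_pairs(art, br$bronchi, hosts, lung, slice_no = 9L)
  expect_length(pairs, 1L)
  p <- pairs[[1]]
  expect_equal(p$slice_no, 9L)
  expect_true(p$discrete)
  # coordinate is the half-up-rounded midpoint of the two centroids
  expect_equal(p$x, as.integer(floor((p$bronchus$centroid["x"] +
                                        p$artery$centroid["x"]) / 2 + 0.5)))
  # bronchus and artery pixel sets are disjoint; the hole is enclosed
  ap <- paste(p$artery$pixels[, 1], p$artery$pixels[, 2])
  bp <- paste(p$bronchus$pixels[, 1], p$bronchus$pixels[, 2])
  expect_length(intersect(ap, bp), 0L)
  dil <- bapair:::.dilate1(p$bronchus$pixels, dim(img))
  hostpix <- paste(p$host$pixels[, 1], p$host$pixels[, 2])
  expect_gt(length(intersect(paste(dil[, 1], dil[, 2]), hostpix)), 0L)
})

test_that("a bronchus without an overlapping artery yields no pair", {
  img <- mk_scene(with_artery = FALSE)
  art <- run_artery_stage(img)
  hosts <- extract_adjacent_objects(art$updated_clean, art)
  hm <- records_to_mask(hosts, dim(img))
  br <- detect_potential_bronchi(hm)
  pairs <- extract_ba_pairs(art, br$bronchi, hosts,
                            matrix(TRUE, nrow(img), ncol(img)))
  expect_length(pairs, 0L)
})

test_that("two bronchi sharing one artery give two non-discrete pairs", {
  size <- 200L
  img <- matrix(0, size, size)
  rr <- row(img); cc <- col(img)
  ring <- function(x, y) {
    d2 <- (rr - y)^2 + (cc - x)^2
    img[d2 <= 49 & d2 > 16] <<- 100
  }
  ring(60, 60); ring(86, 60)
  img[(rr - 60)^2 + (cc - 73)^2 <= 49] <- 225   # artery between the rings
  art <- run_artery_stage(img)
  hosts <- extract_adjacent_objects(art$updated_clean, art)
  hm <- records_to_mask(hosts, dim(img))
  br <- detect_potential_bronchi(hm)
  pairs <- extract_ba_pairs(art, br$bronchi, hosts,
                            matrix(TRUE, size, size))
  expect_length(pairs, 2L)
  expect_false(pairs[[1]]$discrete)
  expect_false(pairs[[2]]$discrete)
  expect_equal(pairs[[1]]$artery$label, pairs[[2]]$artery$label)
})

test_that("phantom slices give exactly the planted number of pairs", {
  ph <- generate_slice(phantom_spec(seed = 21, noise_sigma = 0))
  res <- suppressMessages(process_slice(ph$image, slice_no = 21L))
  expect_length(res$pairs, nrow(ph$truth$pairs))
  expect_lte(length(res$pairs), length(res$bronchi))
  sc <- score_detection(ph$truth, res$pairs)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  sides <- vapply(res$pairs, `[[`, character(1), "lung_side")
  expect_true(all(sides %in% c("left", "right")))
  # planted bronchus centres left of the midline are the patient's right lung
  for (p in res$pairs)
    expect_equal(p$lung_side, if (p$x <= 256) "right" else "left")
})
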