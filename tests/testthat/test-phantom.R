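test_that("phantom generation is fully determined by the seed", {
  a <- generate_slice(phantom_spec(seed = 7))
  b <- generate_slice(phantom_spec(seed = 7))
  expect_identical(a$image, b$image)
  expect_identical(a$truth$pairs, b$truth$pairs)
  c <- generate_slice(phantom_spec(seed = 8))
  expect_false(identical(a$image, c$image))
  # generation does not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(3)
  set.seed(123); invisible(generate_slice(phantom_spec(seed = 7)))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("phantom geometry honours its specification", {
  spec <- phantom_spec(seed = 5, n_pairs = 3, noise_sigma = 0)
  ph <- generate_slice(spec)
  expect_equal(dim(ph$image), c(512L, 512L))
  expect_equal(nrow(ph$truth$pairs), 3L)
  tp <- ph$truth$pairs
  expect_true(all(tp$lumen_radius >= 3 & tp$lumen_radius <= 6))
  expect_true(all(tp$artery_radius >= 5 & tp$artery_radius <= 9))
  expect_equal(tp$true_BADR, tp$lumen_radius / tp$artery_radius)
  # every planted pair lies inside the lung mask
  for (i in seq_len(nrow(tp))) {
    expect_true(ph$truth$lung_mask[round(tp$bronchus_y[i]),
                                   round(tp$bronchus_x[i])])
    expect_true(ph$truth$lung_mask[round(tp$artery_y[i]),
                                   round(tp$artery_x[i])])
    # pair members touch (tangent with 1 px overlap)
    d <- sqrt((tp$bronchus_x[i] - tp$artery_x[i])^2 +
                (tp$bronchus_y[i] - tp$artery_y[i])^2)
    expect_lt(abs(d - (tp$lumen_radius[i] + 3 + tp$artery_radius[i] - 1)),
              1e-6)
  }
  # an over-full specification fails loudly
  expect_error(generate_slice(phantom_spec(seed = 1, n_pairs = 60,
                                           noise_sigma = 0)),
               "do not fit")
})

test_that("noise-free end-to-end run recovers the planted pairs", {
  ph <- generate_slice(phantom_spec(seed = 2, noise_sigma = 0))
  res <- suppressMessages(process_slice(ph$image))
  sc <- score_detection(ph$truth, res$pairs)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_true(all(sc$ratio_errors <= 0.1))
})

test_that("oversized planted arteries are never detected", {
  # a disk of radius 12 has ~450 px, beyond the 300 px artery gate
  img <- matrix(0, 200, 200)
  img[(row(img) - 100)^2 + (col(img) - 100)^2 <= 12^2] <- 225
  img[(row(img) - 50)^2 + (col(img) - 50)^2 <= 20^2] <- 90
  res <- detect_potential_arteries(as_gray_image(img))
  expect_length(res$kept, 0L)
  expect_true(res$discarded_mask[100, 100])
})

test_that("detection scoring counts matches, misses and false positives", {
  truth <- list(pairs = data.frame(
    bronchus_x = c(50, 150, 50, 150), bronchus_y = c(50, 50, 150, 150),
    artery_x = c(60, 160, 60, 160), artery_y = c(50, 50, 150, 150),
    true_BADR = c(0.5, 0.6, 0.7, 0.8)))
  mk_det <- function(bx, by, ax, ay, badr) {
    list(bronchus = list(centroid = c(x = bx, y = by)),
         artery = list(centroid = c(x = ax, y = ay)),
         measurement = list(BADR = badr))
  }
  # perfect detection
  det4 <- lapply(1:4, function(i) mk_det(truth$pairs$bronchus_x[i],
                                         truth$pairs$bronchus_y[i],
                                         truth$pairs$artery_x[i],
                                         truth$pairs$artery_y[i],
                                         truth$pairs$true_BADR[i]))
  s <- score_detection(truth, det4)
  expect_equal(s$recall, 1)
  expect_equal(s$precision, 1)
  expect_equal(s$ratio_MAE, 0)

  # 2 of 4 found plus 1 false positive: recall 0.5, precision 2/3
  det3 <- c(det4[1:2], list(mk_det(300, 300, 310, 300, 0.5)))
  s2 <- score_detection(truth, det3)
  expect_equal(s2$recall, 0.5)
  expect_equal(s2$precision, 2 / 3)

  # zero detections: vacuous precision 1.0 with a flag
  s3 <- score_detection(truth, list())
  expect_equal(s3$recall, 0)
  expect_equal(s3$precision, 1.0)
  expect_true(s3$no_detections)
})
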