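test_that("PNG slices round-trip and normalize to 512x512", {
  tmp <- withr::local_tempdir()
  # identity case: all-zero 512x512
  z <- file.path(tmp, "zero.png")
  png::writePNG(matrix(0, 512, 512), z)
  expect_equal(read_slice(z, "png"), matrix(0, 512, 512))

  # constant is invariant under resampling
  cpath <- file.path(tmp, "const.png")
  png::writePNG(matrix(100 / 255, 256, 256), cpath)
  g <- read_slice(cpath, "png")
  expect_equal(dim(g), c(512L, 512L))
  expect_true(all(g == 100))

  # re-encoding a gray image reproduces identical pixels
  set.seed(42)
  img <- as_gray_image(matrix(sample(0:255, 512 * 512, replace = TRUE), 512))
  p <- file.path(tmp, "rt.png")
  write_gray_png(img, p)
  expect_identical(read_slice(p, "png"), img)

  # normalization preserves intensity ordering
  src <- matrix(rep(seq(0, 255, length.out = 64), each = 64), 64, 64)
  sp <- file.path(tmp, "ramp.png")
  png::writePNG(src / 255, sp)
  rs <- read_slice(sp, "png")
  expect_true(all(diff(rs[256, ]) >= 0))

  # color input is rejected
  cp <- file.path(tmp, "color.png")
  png::writePNG(array(runif(12), c(2, 2, 3)), cp)
  expect_error(read_slice(cp, "png"), "color")
  expect_error(read_slice(file.path(tmp, "missing.png"), "png"), "missing.png")
})

test_that("DICOM slices are windowed and rescaled to [0, 255]", {
  tmp <- withr::local_tempdir()
  # stored+intercept covers HU [-1000, 400]; window (-500, 1400) clips the
  # top then min-max rescale maps the extremes to exactly 0 and 255
  hu <- matrix(round(seq(-1000, 400, length.out = 32 * 32)), 32, 32,
               byrow = TRUE)
  f <- file.path(tmp, "ct.dcm")
  write_test_dicom(f, stored = hu + 1024, intercept = -1024,
                   window_center = -500, window_width = 1400, instance = 3L)
  d <- read_dicom(f)
  expect_equal(d$pixels, hu)
  expect_equal(d$window, c(-500, 1400))
  expect_equal(d$instance, 3L)
  g <- read_slice(f, "dicom")
  expect_equal(dim(g), c(512L, 512L))
  expect_equal(min(g), 0)
  expect_equal(max(g), 255)

  # stack ordering follows InstanceNumber, not filename: the file named
  # first lexicographically carries instance 2 and a descending ramp
  ramp <- matrix(seq_len(64), 8, 8, byrow = TRUE)
  write_test_dicom(file.path(tmp, "a.dcm"), 65 - ramp, instance = 2L)
  write_test_dicom(file.path(tmp, "b.dcm"), ramp, instance = 1L)
  file.remove(f)
  st <- read_slice_stack(tmp, "dicom")
  expect_equal(length(st), 2L)
  expect_equal(st$slices[[1]][1, 1], 0)     # ascending ramp first
  expect_equal(st$slices[[2]][1, 1], 255)
})

test_that("pair table has the fixed schema, ordering and formatting", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "pairs.csv")
  cols <- c("pair_id", "slice_no", "x", "y", "lung_side",
            paste0("BD", 1:4), "ABD", paste0("AD", 1:4), "AAD", "BADR",
            "BAr", "AAr", "BAAR")

  # empty input -> header-only CSV
  write_pair_table(list(), path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_equal(strsplit(lines, ",")[[1]], cols)

  mk_pair <- function(slice, x, y, bd, ad, bar, aar) {
    list(pair_id = NA, slice_no = slice, x = x, y = y, lung_side = "right",
         measurement = compute_ratios(bd, ad, bar, aar))
  }
  p1 <- mk_pair(282, 177, 258, c(4.12, 3.00, 6.01, 6.01),
                c(9.16, 8.17, 10.00, 10.17), 12, 61)
  p2 <- mk_pair(281, 179, 259, c(5, 5, 5, 5), c(8, 8, 8, 8), 16, 50)
  df <- write_pair_table(list(p1, p2), path)
  expect_equal(df$slice_no, c(281L, 282L))   # sorted by slice first
  expect_equal(df$BADR[2], "0.51")
  expect_equal(df$BAr[2], "12.00")
  raw <- read.csv(path, colClasses = "character")
  expect_equal(names(raw), cols)
  expect_equal(nrow(raw), 2L)
})

test_that("overlays mark bronchi red and arteries blue on grayscale", {
  tmp <- withr::local_tempdir()
  img <- as_gray_image(matrix(60, 20, 20))
  mask <- matrix(0L, 20, 20)
  mask[5, 5] <- 1L    # bronchus
  mask[10, 10] <- 2L  # artery
  p <- file.path(tmp, "ov.png")
  write_overlay(img, mask, p)
  rgb <- png::readPNG(p)
  expect_equal(rgb[5, 5, ] * 255, c(255, 0, 0))
  expect_equal(rgb[10, 10, ] * 255, c(0, 0, 255))
  expect_equal(rgb[1, 1, ] * 255, c(60, 60, 60))

  # empty mask reproduces the grayscale input on all three channels
  write_overlay(img, matrix(0L, 20, 20), p)
  rgb <- png::readPNG(p)
  for (k in 1:3) expect_true(all(rgb[, , k] * 255 == 60))

  expect_error(write_overlay(img, matrix(0L, 5, 5), p), "shape")
})
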