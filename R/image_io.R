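#' Read one axial slice as a gray image
#'
#' PNG input (8- or 16-bit grayscale) is rescaled to `[0, 255]`; DICOM
#' input is windowed (centre/width from the argument, else the file's
#' stored window, else full-range) and min-max rescaled to `[0, 255]`.
#' Slices are resampled to 512x512 with bilinear interpolation. No patient
#' metadata is retained in the returned object.
#'
#' @param path file path.
#' @param format `"png"` or `"dicom"`.
#' @param window optional `c(center, width)` for DICOM windowing.
#' @param size target side length in px (default 512).
#' @return gray-image matrix (`size` x `size`, intensities 0..255).
#' @export
read_slice <- function(path, format = c("png", "dicom"), window = NULL,
                       size = 512L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read slice: no such file: ", path)
  if (format == "png") {
    img <- tryCatch(png::readPNG(path),
                    error = function(e) stop("cannot read PNG ", path, ": ",
                                             conditionMessage(e)))
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] == 2L) img <- img[, , 1]   # gray + alpha
      else stop("color PNG input is not supported: ", path)
    }
    g <- img * 255
  } else {
    d <- read_dicom(path)
    g <- .window_rescale(d$pixels, window %||% d$window)
  }
  .resample_to(as_gray_image(g), size)
}

.window_rescale <- function(hu, window) {
  if (!is.null(window) && length(window) == 2L && window[2] > 0) {
    lo <- window[1] - window[2] / 2
    hi <- window[1] + window[2] / 2
    hu <- pmin(pmax(hu, lo), hi)
  }
  rng <- range(hu)
  if (rng[2] > rng[1]) (hu - rng[1]) / (rng[2] - rng[1]) * 255
  else hu * 0
}

.resample_to <- function(img, size) {
  if (nrow(img) == size && ncol(img) == size) return(img)
  as_gray_image(as.matrix(EBImage::resize(img / 255, w = size, h = size)) * 255)
}

#' Read an ordered slice stack from a directory
#'
#' PNG stacks are ordered by lexicographic filename; DICOM stacks by
#' InstanceNumber (falling back to filename when absent).
#'
#' @inheritParams read_slice
#' @param dir directory containing the series.
#' @param pattern filename filter (default by format extension).
#' @return a [slice_stack()].
#' @export
read_slice_stack <- function(dir, format = c("png", "dicom"), window = NULL,
                             size = 512L, pattern = NULL) {
  format <- match.arg(format)
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  pattern <- pattern %||% if (format == "png") "\\.png$" else "\\.dcm$"
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (!length(files)) stop("no ", format, " slices found in ", dir)
  if (format == "dicom") {
    inst <- vapply(files, function(f) {
      n <- read_dicom(f)$instance
      if (is.na(n)) -1L else n
    }, integer(1))
    if (all(inst >= 0L)) files <- files[order(inst)]
  }
  slices <- lapply(files, read_slice, format = format, window = window,
                   size = size)
  slice_stack(slices, slice_ids = seq_along(slices))
}

#' Write the BA pair table as CSV
#'
#' One row per pair with the Table-style schema: `pair_id, slice_no, x, y,
#' lung_side, BD1..BD4, ABD, AD1..AD4, AAD, BADR, BAr, AAr, BAAR`. Rows are
#' sorted by `(slice_no, x, y)`; measurements print with fixed two-decimal
#' formatting (half-up by default, truncation available for comparison with
#' tools that truncate).
#'
#' @param pairs list of BA pair records (each holding a `measurement`), or
#'   an empty list for a header-only file.
#' @param path output CSV path.
#' @param rounding `"half_up"` or `"truncate"`.
#' @return the written data frame, invisibly.
#' @export
write_pair_table <- function(pairs, path, rounding = "half_up") {
  df <- pairs_to_table(pairs, rounding = rounding)
  out <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write table ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(out))
  write.csv(df, out, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Flatten BA pair records into a table
#'
#' @inheritParams write_pair_table
#' @return data frame (character measurement columns, fixed 2-decimal
#'   formatting), sorted by `(slice_no, x, y)`.
#' @export
pairs_to_table <- function(pairs, rounding = "half_up") {
  cols <- c("pair_id", "slice_no", "x", "y", "lung_side",
            paste0("BD", 1:4), "ABD", paste0("AD", 1:4), "AAD", "BADR",
            "BAr", "AAr", "BAAR")
  if (!length(pairs)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        check.names = FALSE)
    return(df)
  }
  fmt <- function(v) sprintf("%.2f", round_fixed(v, 2L, rounding))
  rows <- lapply(pairs, function(p) {
    m <- p$measurement
    data.frame(pair_id = p$pair_id, slice_no = p$slice_no, x = p$x, y = p$y,
               lung_side = p$lung_side %||% NA_character_,
               BD1 = fmt(m$BD[1]), BD2 = fmt(m$BD[2]), BD3 = fmt(m$BD[3]),
               BD4 = fmt(m$BD[4]), ABD = fmt(m$ABD),
               AD1 = fmt(m$AD[1]), AD2 = fmt(m$AD[2]), AD3 = fmt(m$AD[3]),
               AD4 = fmt(m$AD[4]), AAD = fmt(m$AAD), BADR = fmt(m$BADR),
               BAr = fmt(m$BAr), AAr = fmt(m$AAr), BAAR = fmt(m$BAAR),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$slice_no, df$x, df$y), , drop = FALSE]
  df$pair_id <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Write a color overlay of the detected pairs
#'
#' Writes an RGB PNG: bronchus pixels pure red, artery pixels pure blue,
#' everything else the grayscale slice.
#'
#' @param image gray-image matrix.
#' @param pair_mask integer matrix of the same shape: 0 background,
#'   1 bronchus, 2 artery.
#' @param path output PNG path.
#' @export
write_overlay <- function(image, pair_mask, path) {
  if (!all(dim(image) == dim(pair_mask)))
    stop("pair_mask shape does not match the image")
  g <- image / 255
  rgb <- array(rep(g, 3L), dim = c(dim(image), 3L))
  br <- pair_mask == 1L
  ar <- pair_mask == 2L
  r <- rgb[, , 1]; gg <- rgb[, , 2]; b <- rgb[, , 3]
  r[br] <- 1; gg[br] <- 0; b[br] <- 0
  r[ar] <- 0; gg[ar] <- 0; b[ar] <- 1
  rgb[, , 1] <- r; rgb[, , 2] <- gg; rgb[, , 3] <- b
  png::writePNG(rgb, path)
  invisible(path)
}

#' Build the 0/1/2 pair mask from BA pair records
#'
#' @param pairs list of BA pair records.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return integer matrix: 0 background, 1 bronchus, 2 artery.
#' @export
pair_mask <- function(pairs, dim) {
  m <- matrix(0L, dim[1], dim[2])
  for (p in pairs) {
    m[p$bronchus$pixels] <- 1L
    m[p$artery$pixels] <- 2L
  }
  m
}

#' Write a gray image as 8-bit PNG
#'
#' @param img gray-image matrix.
#' @param path output path.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(img / 255, path)
  invisible(path)
}
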