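#' Intensity histogram of a lung image, zeros excluded
#'
#' Counts pixels per intensity 0..255 but forces the 0 bin to zero: in a
#' lung-masked slice the background dominates the histogram and would hide
#' the tissue distribution entirely.
#'
#' @param img gray-image matrix.
#' @return integer vector of length 256 (index `i` holds the count of
#'   intensity `i - 1`); the first entry is always 0.
#' @export
intensity_histogram <- function(img) {
  h <- tabulate(as.integer(img) + 1L, nbins = 256L)
  h[1] <- 0L
  h
}

#' Number-of-pixels threshold (NPT) from a lung histogram
#'
#' The count axis `[0, peak]` of the zero-excluded histogram is divided into
#' `n_bands` equal bands; the NPT is the lower limit of the top band, i.e.
#' `ceiling((n_bands - 1) * peak / n_bands)`. Intensities whose counts reach
#' the NPT form the "populated" part of the histogram from which the
#' cleaning threshold is read. The highest-peak intensity (HPI) breaks ties
#' towards the smallest intensity.
#'
#' @param hist length-256 count vector from [intensity_histogram()].
#' @param n_bands number of horizontal bands (default 3).
#' @return list with `HPI` (intensity of the maximal count), `peak_height`
#'   and `NPT`.
#' @export
compute_npt <- function(hist, n_bands = 3L) {
  stopifnot(length(hist) == 256L)
  counts <- hist[-1]
  if (all(counts <= 0)) stop("empty lung histogram")
  k <- which.max(counts)        # first maximum = smallest intensity on tie
  peak <- counts[k]
  list(HPI = as.integer(k),
       peak_height = as.integer(peak),
       NPT = as.integer(ceiling((n_bands - 1) * peak / n_bands)))
}

#' Pixel-intensity threshold (PIT) from the NPT
#'
#' The PIT is the highest intensity whose count reaches the NPT. If no
#' intensity qualifies the PIT is 0 and cleaning becomes a no-op.
#'
#' @param hist length-256 count vector from [intensity_histogram()].
#' @param npt count threshold from [compute_npt()].
#' @return integer intensity threshold in `[0, 255]`.
#' @export
compute_pit <- function(hist, npt) {
  stopifnot(length(hist) == 256L)
  qual <- which(hist[-1] >= npt)
  if (!length(qual)) return(0L)
  as.integer(max(qual))
}

#' Histogram-analysis image cleaning
#'
#' Removes low-intensity clutter from a lung-masked slice: every pixel with
#' intensity at or below the PIT is set to 0 (the boundary is inclusive).
#' The surviving pixels keep their original intensities, so cleaning is
#' pixel-wise monotone non-increasing.
#'
#' @param lung_img gray image from [segment_lungs()].
#' @param n_bands histogram band count for the NPT rule (default 3).
#' @return list with `clean_img` and `thresholds` (a list holding the
#'   zero-excluded `hist`, `HPI`, `peak_height`, `NPT` and `PIT`).
#' @export
clean_image <- function(lung_img, n_bands = 3L) {
  h <- intensity_histogram(lung_img)
  npt <- compute_npt(h, n_bands = n_bands)
  pit <- compute_pit(h, npt$NPT)
  clean <- lung_img
  clean[clean <= pit] <- 0
  list(clean_img = clean,
       thresholds = list(hist = h, HPI = npt$HPI,
                         peak_height = npt$peak_height,
                         NPT = npt$NPT, PIT = pit))
}
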