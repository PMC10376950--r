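#' Balanced histogram threshold
#'
#' Automatic binarization threshold from the balanced-histogram iteration:
#' the histogram interval carries a moving centre; at each step one outer
#' bin is removed from the heavier side and the centre is re-adjusted to the
#' interval midpoint, until the interval collapses or both sides run out of
#' weight. Applied to the cleaned lung image it isolates the brightest
#' structures (candidate arteries) from the remaining mid-intensity tissue.
#'
#' The zero bin is excluded (the cleaned image is mostly background, which
#' would swamp the balance), mirroring the zero exclusion of the histogram
#' cleaning stage. An image with a single nonzero intensity `v` returns
#' `v - 1`, so binarization keeps everything.
#'
#' @param x gray-image matrix, or a length-256 count vector (intensity 0 in
#'   the first bin; the 0 bin is ignored either way).
#' @return integer threshold `t`; binarization keeps pixels `> t`.
#' @export
balanced_histogram_threshold <- function(x) {
  h <- if (is.matrix(x)) intensity_histogram(x) else as.numeric(x)
  stopifnot(length(h) == 256L)
  h[1] <- 0
  nz <- which(h > 0) - 1L            # intensities with mass
  if (!length(nz)) stop("balanced histogram threshold needs nonzero pixels")
  i_s <- min(nz); i_e <- max(nz)
  if (i_s == i_e) return(as.integer(i_s - 1L))
  i_m <- (i_s + i_e) %/% 2L           # centre = midpoint of the interval
  w_l <- sum(h[(i_s:i_m) + 1L])
  w_r <- sum(h[((i_m + 1L):i_e) + 1L])
  while (i_s <= i_e) {
    if (w_r > w_l) {                  # right side heavier: drop its outer bin
      w_r <- w_r - h[i_e + 1L]
      i_e <- i_e - 1L
    } else {
      w_l <- w_l - h[i_s + 1L]
      i_s <- i_s + 1L
    }
    if (i_s > i_e) break
    new_m <- (i_s + i_e) %/% 2L
    if (new_m > i_m) {                # centre moved right: bin changes side
      w_l <- w_l + h[new_m + 1L]
      w_r <- w_r - h[new_m + 1L]
    } else if (new_m < i_m) {
      w_l <- w_l - h[i_m + 1L]
      w_r <- w_r + h[i_m + 1L]
    }
    i_m <- new_m
    if (w_l <= 0 && w_r <= 0) break   # spike histograms: both sides exhausted
  }
  as.integer(i_m)
}

#' Detect potential arteries in a cleaned slice
#'
#' Bright regions are isolated by [balanced_histogram_threshold()] and
#' denoised by a 3x3 morphological opening; the surviving 8-connected
#' components are screened with the four artery conditions
#' ([artery_gates()]: `10 <= area < 300`, circularity > 0.3, bounding-box
#' ratio > 0.4, enclosed-circle ratio > 0.4). Components failing any
#' condition form the discarded-bright-object mask and are erased from the
#' cleaned image, yielding the updated clean image used by the pairing
#' stage.
#'
#' @param clean_img cleaned gray image from [clean_image()].
#' @param gates artery screening thresholds (default [artery_gates()]).
#' @return list with `kept` (list of [component_record()]s: the potential
#'   arteries), `discarded_mask` and `bright_mask` (logical matrices),
#'   `threshold` (the BHT value) and `updated_clean` (gray image with
#'   discarded bright objects zeroed).
#' @export
detect_potential_arteries <- function(clean_img, gates = artery_gates()) {
  out_empty <- list(kept = list(),
                    discarded_mask = matrix(FALSE, nrow(clean_img), ncol(clean_img)),
                    bright_mask = matrix(FALSE, nrow(clean_img), ncol(clean_img)),
                    threshold = NA_integer_,
                    updated_clean = clean_img)
  if (!any(clean_img > 0)) return(out_empty)
  t_bht <- balanced_histogram_threshold(clean_img)
  bright <- clean_img > t_bht
  if (any(bright)) {
    opened <- as.matrix(EBImage::opening(bright * 1,
                                         EBImage::makeBrush(3, "box"))) > 0
  } else {
    opened <- bright
  }
  lab <- label_components(opened)
  recs <- component_records(lab)
  pass <- vapply(recs, passes_conditions, logical(1), gates = gates)
  kept <- recs[pass]
  discarded <- matrix(FALSE, nrow(clean_img), ncol(clean_img))
  for (r in recs[!pass]) discarded[r$pixels] <- TRUE
  updated <- clean_img
  updated[discarded] <- 0
  list(kept = kept, discarded_mask = discarded, bright_mask = opened,
       threshold = t_bht, updated_clean = updated)
}
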