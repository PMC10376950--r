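#' Edge-preserving total-variation denoising
#'
#' Rudin-Osher-Fatemi total-variation minimisation by Chambolle's dual
#' projection algorithm. TV denoising flattens noise inside homogeneous
#' regions while keeping edges sharp, which matters here because the later
#' stages threshold on intensity steps (lung/body, vessel/parenchyma).
#' The image is processed on a `[0, 1]` scale and re-quantised to 8 bits.
#'
#' @param img gray-image matrix.
#' @param weight regularisation weight (> 0); larger values smooth more.
#'   The default 0.1 removes typical CT reconstruction noise without
#'   displacing the lung boundary.
#' @param eps relative energy-change stopping tolerance.
#' @param max_iter iteration cap.
#' @return denoised gray-image matrix; its total variation never exceeds the
#'   input's.
#' @export
tv_denoise <- function(img, weight = 0.1, eps = 2e-4, max_iter = 100L) {
  stopifnot(weight > 0)
  x <- img / 255
  h <- nrow(x); w <- ncol(x)
  p1 <- matrix(0, h, w); p2 <- matrix(0, h, w)
  d <- matrix(0, h, w)
  out <- x
  e_init <- NULL; e_prev <- NULL
  tau <- 1 / 4
  for (i in seq_len(max_iter)) {
    if (i > 1L) {
      d <- -(p1 + p2)
      d[-1, ] <- d[-1, ] + p1[-h, ]
      d[, -1] <- d[, -1] + p2[, -w]
      out <- x + d
    }
    e <- sum(d^2)
    g1 <- matrix(0, h, w); g2 <- matrix(0, h, w)
    g1[-h, ] <- out[-1, ] - out[-h, ]
    g2[, -w] <- out[, -1] - out[, -w]
    nrm <- sqrt(g1^2 + g2^2)
    e <- (e + weight * sum(nrm)) / length(x)
    nrm <- nrm * (tau / weight) + 1
    p1 <- (p1 - tau * g1) / nrm
    p2 <- (p2 - tau * g2) / nrm
    if (is.null(e_init)) {
      e_init <- e; e_prev <- e
    } else {
      if (abs(e_prev - e) < eps * e_init) break
      e_prev <- e
    }
  }
  as_gray_image(out * 255)
}

#' Conditional brightness/contrast (alpha-beta) correction
#'
#' Affine intensity correction `clip(alpha * img + beta)` that pulls the
#' image mean towards a target so that Otsu binarization behaves uniformly
#' across slices with different exposure. The correction is conditional: it
#' is skipped when the mean is already within `tol` of the target. The gain
#' is `alpha = clamp(target/mean, 0.5, 2)` (1 for an all-zero image) and the
#' offset `beta = target - alpha * mean`, so the pre-clipping output mean
#' equals the target exactly.
#'
#' @param img gray-image matrix.
#' @param target target mean intensity (default 110, mid-gray for a
#'   thoracic slice where the bright body on a dark background dominates).
#' @param tol no-op band around the target (default 15).
#' @return corrected gray-image matrix.
#' @export
alpha_beta_correct <- function(img, target = 110, tol = 15) {
  stopifnot(length(img) > 0)
  m <- mean(img)
  if (abs(m - target) <= tol) return(as_gray_image(img))
  alpha <- if (m > 0) min(max(target / m, 0.5), 2) else 1
  beta <- target - alpha * m
  as_gray_image(alpha * img + beta)
}

#' Segment the lung fields of an axial CT slice
#'
#' Six-step lung extraction: (1) total-variation denoising, (2) conditional
#' alpha-beta correction, (3) Otsu binarization (the bright body becomes
#' foreground, the dark lung fields background), (4) largest-contour
#' detection (the biggest 8-connected foreground component, i.e. the body,
#' is kept; bright clutter inside the lungs is dropped), (5) inversion and
#' flood fill from the image corners (the exterior background is removed,
#' leaving the lung fields), and (6) hole filling of each lung component by
#' morphological reconstruction (vessels and airway walls inside the lungs
#' must stay part of the lung field). At most the two largest candidate
#' regions are kept, one per lung (they merge near the carina on some
#' slices, so a single component is also valid). The lung image is the
#' original slice masked by the lung mask, so retained pixels keep their
#' original intensities.
#'
#' @param img gray-image matrix (the original slice).
#' @param config a [pipeline_config()]; uses `tv_weight`, `ab_target`,
#'   `ab_tol` and `min_lung_frac`.
#' @return list with `lung_mask` (logical matrix), `lung_img` (gray image,
#'   0 outside the mask), and `no_lung` (flag: lung area below
#'   `min_lung_frac` of the slice, e.g. a slice outside the thorax).
#'   A blank slice yields an empty mask with a warning, never an error.
#' @export
segment_lungs <- function(img, config = pipeline_config()) {
  empty <- function(msg) {
    warning(msg, call. = FALSE)
    list(lung_mask = matrix(FALSE, nrow(img), ncol(img)),
         lung_img = as_gray_image(img * 0),
         no_lung = TRUE)
  }
  if (all(img == img[1])) return(empty("blank slice: no lung fields found"))

  den <- tv_denoise(img, weight = config$tv_weight)
  cor <- alpha_beta_correct(den, target = config$ab_target, tol = config$ab_tol)
  if (all(cor == cor[1])) return(empty("blank slice after correction"))
  thr <- EBImage::otsu(cor / 255, range = c(0, 1), levels = 256)
  fg <- cor / 255 > thr
  if (!any(fg)) return(empty("no foreground after Otsu binarization"))

  lab <- label_components(fg)
  areas <- tabulate(lab[lab > 0L])
  body <- lab == which.max(areas)          # ties: smallest label index
  inv <- !body
  ilab <- label_components(inv)
  h <- nrow(img); w <- ncol(img)
  corner_lab <- unique(c(ilab[1, 1], ilab[1, w], ilab[h, 1], ilab[h, w]))
  corner_lab <- corner_lab[corner_lab > 0L]
  interior <- inv & !(matrix(ilab %in% corner_lab, h, w))
  if (!any(interior)) return(empty("no lung fields inside the body contour"))

  filled <- as.matrix(EBImage::fillHull(interior * 1)) > 0
  flab <- label_components(filled)
  fareas <- tabulate(flab[flab > 0L])
  keep <- order(fareas, decreasing = TRUE)[seq_len(min(2L, length(fareas)))]
  lung_mask <- matrix(flab %in% keep, h, w)

  no_lung <- sum(lung_mask) < config$min_lung_frac * length(img)
  list(lung_mask = lung_mask,
       lung_img = as_gray_image(img * lung_mask),
       no_lung = no_lung)
}
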