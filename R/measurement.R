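#' Four diameters through the component centre
#'
#' Casts lines through the component centroid at 0, 45, 90 and 135 degrees
#' (image coordinates) and measures, for each, the maximal contiguous run
#' of component pixels containing the centre. The run length is Euclidean:
#' a diameter spanning `n` pixels measures `1 + (n - 1) * s` px where `s`
#' is the step length (1 on the axes, sqrt(2) on the diagonals), i.e. the
#' distance between the run's end-pixel centres plus one pixel of extent.
#' Using the contiguous run (a chord) rather than the full line-object
#' intersection keeps C-shaped artefacts from inflating the measurement.
#' If the rounded centroid falls outside the component (possible for
#' crescents), the nearest component pixel is used as centre.
#'
#' @param component a [component_record()].
#' @return named numeric vector `c(d0, d45, d90, d135)` in px.
#' @export
measure_diameters <- function(component) {
  pix <- component$pixels
  rr <- range(pix[, 1]); cr <- range(pix[, 2])
  h <- rr[2] - rr[1] + 1L; w <- cr[2] - cr[1] + 1L
  m <- matrix(FALSE, h, w)
  lr <- pix[, 1] - rr[1] + 1L
  lc <- pix[, 2] - cr[1] + 1L
  m[cbind(lr, lc)] <- TRUE
  r0 <- floor(component$centroid["y"] - rr[1] + 1 + 0.5)
  c0 <- floor(component$centroid["x"] - cr[1] + 1 + 0.5)
  r0 <- min(max(r0, 1L), h); c0 <- min(max(c0, 1L), w)
  if (!m[r0, c0]) {
    k <- which.min((lr - r0)^2 + (lc - c0)^2)
    r0 <- lr[k]; c0 <- lc[k]
  }
  run <- function(dr, dc) {
    n <- 1L
    r <- r0 + dr; c <- c0 + dc
    while (r >= 1L && r <= h && c >= 1L && c <= w && m[r, c]) {
      n <- n + 1L; r <- r + dr; c <- c + dc
    }
    r <- r0 - dr; c <- c0 - dc
    while (r >= 1L && r <= h && c >= 1L && c <= w && m[r, c]) {
      n <- n + 1L; r <- r - dr; c <- c - dc
    }
    step <- sqrt(dr^2 + dc^2)
    1 + (n - 1L) * step
  }
  # angles in image coordinates: 0 = +x, 45 = down-right diagonal, 90 = +y
  c(d0 = run(0L, 1L), d45 = run(1L, 1L), d90 = run(1L, 0L),
    d135 = run(1L, -1L))
}

#' BA ratios from diameters and areas
#'
#' The average bronchus diameter `ABD` and average artery diameter `AAD`
#' are the arithmetic means of the four chords; the diameter ratio is
#' `BADR = ABD / AAD` and the area ratio `BAAR = BAr / AAr` where the areas
#' are pixel counts. The bronchus diameters are inner (lumen) diameters.
#' Values are kept at full precision; table output formats to two decimals
#' (see [write_pair_table()]).
#'
#' @param bd,ad numeric length-4 vectors of bronchus and artery chord
#'   lengths in px.
#' @param b_area,a_area bronchus (lumen) and artery areas in px.
#' @return object of class `"ba_measurement"`: list with `BD`, `AD`, `ABD`,
#'   `AAD`, `BADR`, `BAr`, `AAr`, `BAAR`.
#' @export
compute_ratios <- function(bd, ad, b_area, a_area) {
  stopifnot(length(bd) == 4L, length(ad) == 4L)
  abd <- mean(bd); aad <- mean(ad)
  if (aad <= 0 || a_area <= 0)
    stop("artery diameter and area must be positive")
  structure(list(BD = as.numeric(bd), AD = as.numeric(ad),
                 ABD = abd, AAD = aad, BADR = abd / aad,
                 BAr = as.numeric(b_area), AAr = as.numeric(a_area),
                 BAAR = b_area / a_area),
            class = "ba_measurement")
}

#' @export
print.ba_measurement <- function(x, ...) {
  cat(sprintf("BA measurement: ABD=%.2f AAD=%.2f BADR=%.2f  BAr=%.2f AAr=%.2f BAAR=%.2f\n",
              x$ABD, x$AAD, x$BADR, x$BAr, x$AAr, x$BAAR))
  invisible(x)
}

#' Measure one BA pair
#'
#' Convenience wrapper: measures the four diameters of the bronchus lumen
#' and the artery and derives the ratios.
#'
#' @param bronchus,artery [component_record()]s (the bronchus is the inner
#'   lumen component).
#' @return a `"ba_measurement"`.
#' @export
measure_pair <- function(bronchus, artery) {
  compute_ratios(measure_diameters(bronchus), measure_diameters(artery),
                 bronchus$area, artery$area)
}

#' Patient-level summary of BA measurements
#'
#' Counts pairs per lung side and aggregates the diameter and area ratios
#' (mean, min, max) across pairs.
#'
#' @param measurements list of `"ba_measurement"` objects.
#' @param pairs matching list of BA pair records (for slice/side counts);
#'   may be `NULL` if side counts are not needed.
#' @return list with `n_pairs`, `n_right`, `n_left`, and `BADR`/`BAAR`
#'   summaries (`mean`, `min`, `max`; absent, i.e. `NULL`, for empty input).
#' @export
summarize_patient <- function(measurements, pairs = NULL) {
  n <- length(measurements)
  sides <- if (is.null(pairs)) character(0)
           else vapply(pairs, function(p) p$lung_side %||% NA_character_,
                       character(1))
  out <- list(n_pairs = n,
              n_right = sum(sides == "right", na.rm = TRUE),
              n_left = sum(sides == "left", na.rm = TRUE))
  if (n == 0L) {
    out$BADR <- NULL; out$BAAR <- NULL
    return(out)
  }
  badr <- vapply(measurements, `[[`, numeric(1), "BADR")
  baar <- vapply(measurements, `[[`, numeric(1), "BAAR")
  out$BADR <- c(mean = mean(badr), min = min(badr), max = max(badr))
  out$BAAR <- c(mean = mean(baar), min = min(baar), max = max(baar))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rounding helpers for table output
#'
#' Fixed two-decimal formatting with either half-up rounding (default) or
#' truncation towards zero.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @param mode `"half_up"` or `"truncate"`.
#' @return numeric vector rounded to `digits` places.
#' @export
round_fixed <- function(x, digits = 2L, mode = c("half_up", "truncate")) {
  mode <- match.arg(mode)
  f <- 10^digits
  if (mode == "half_up") floor(x * f + 0.5 + 1e-9) / f
  else trunc(x * f + sign(x) * 1e-9) / f
}
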