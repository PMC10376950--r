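#' Grayscale working raster
#'
#' The pipeline's working representation of one axial slice is a plain
#' numeric matrix with integer-valued intensities in `[0, 255]`; rows index
#' the image y axis (top to bottom), columns the x axis. `as_gray_image()`
#' rounds, clips and validates an arbitrary numeric matrix into that form.
#'
#' @param x numeric matrix.
#' @return numeric matrix with integer values in `[0, 255]`.
#' @export
as_gray_image <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("a gray image must be a numeric matrix")
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "double"
  x
}

.clip_gray <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

.is_binary_mask <- function(mask, ref = NULL) {
  ok <- is.matrix(mask) && (is.logical(mask) || all(mask %in% c(0, 1)))
  if (ok && !is.null(ref)) ok <- all(dim(mask) == dim(ref))
  ok
}

#' Ordered stack of axial slices
#'
#' Bundles a list of same-shaped gray images with strictly increasing
#' integer slice ids and an optional slice spacing in millimetres.
#'
#' @param slices list of gray-image matrices (see [as_gray_image()]).
#' @param slice_ids integer vector, one id per slice, strictly increasing.
#' @param spacing_mm optional scalar slice thickness/interval in mm.
#' @return object of class `"slice_stack"`.
#' @export
slice_stack <- function(slices, slice_ids = seq_along(slices),
                        spacing_mm = NULL) {
  stopifnot(is.list(slices), length(slices) == length(slice_ids))
  if (length(slices)) {
    dims <- vapply(slices, function(s) dim(s), integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all slices in a stack must have the same shape")
    if (any(diff(as.integer(slice_ids)) <= 0))
      stop("slice_ids must be strictly increasing")
  }
  structure(list(slices = slices, slice_ids = as.integer(slice_ids),
                 spacing_mm = spacing_mm),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  cat(sprintf("slice_stack: %d slice(s)", length(x$slices)))
  if (length(x$slices))
    cat(sprintf(", %dx%d px", nrow(x$slices[[1]]), ncol(x$slices[[1]])))
  if (!is.null(x$spacing_mm)) cat(sprintf(", spacing %.2f mm", x$spacing_mm))
  cat("\n")
  invisible(x)
}

#' @export
length.slice_stack <- function(x) length(x$slices)
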