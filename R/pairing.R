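#' Extract objects adjacent to the potential arteries
#'
#' The updated clean image is binarized (`> 0`) and its 8-connected
#' components are matched against the potential-artery coordinates: a
#' component is kept exactly when its pixel set shares at least one pixel
#' with a kept artery (each kept artery is itself part of the updated clean
#' image, so every artery selects its host component, including any
#' bronchial wall it touches). Components with no artery overlap remain
#' unidentified and are dropped.
#'
#' @param updated_clean gray image from [detect_potential_arteries()].
#' @param arteries result of [detect_potential_arteries()] (or a list with a
#'   `kept` element).
#' @return list of [component_record()]s, the host contours; each record
#'   gains an `artery_labels` element naming the kept arteries it overlaps.
#' @export
extract_adjacent_objects <- function(updated_clean, arteries) {
  kept <- arteries$kept
  lab <- label_components(updated_clean > 0)
  if (!length(kept) || !any(lab > 0L)) return(list())
  keep_lab <- integer(0)
  art_of <- list()
  for (i in seq_along(kept)) {
    ls <- unique(lab[kept[[i]]$pixels])
    ls <- ls[ls > 0L]
    for (l in ls) {
      key <- as.character(l)
      art_of[[key]] <- c(art_of[[key]], i)
    }
    keep_lab <- union(keep_lab, ls)
  }
  keep_lab <- sort(keep_lab)
  recs <- component_records(lab)
  out <- lapply(keep_lab, function(l) {
    r <- recs[[l]]
    r$artery_labels <- art_of[[as.character(l)]]
    r
  })
  out
}

#' Detect potential bronchi as holes of the host contours
#'
#' The host-contour image is binarized, all enclosed holes are filled, and
#' the original binary image is subtracted from the filled mask, leaving
#' only the holes — candidate bronchial lumens. Each hole component is then
#' screened with the four bronchus conditions ([bronchus_gates()]: area
#' > 3 px, circularity > 0.5, enclosed-circle ratio > 0.6, bounding-box
#' ratio > 0.6), so only near-circular lumens survive.
#'
#' @param host_mask logical/0-1 matrix containing only the host contours
#'   (from [extract_adjacent_objects()] records, see [records_to_mask()]).
#' @param gates bronchus screening thresholds (default [bronchus_gates()]).
#' @return list with `hole_mask` (all holes, before screening) and
#'   `bronchi` (list of passing [component_record()]s).
#' @export
detect_potential_bronchi <- function(host_mask, gates = bronchus_gates()) {
  b <- host_mask > 0
  if (!any(b)) {
    return(list(hole_mask = b, bronchi = list()))
  }
  f <- as.matrix(EBImage::fillHull(b * 1)) > 0
  holes <- f & !b
  if (!any(holes)) return(list(hole_mask = holes, bronchi = list()))
  lab <- label_components(holes)
  recs <- component_records(lab)
  pass <- vapply(recs, passes_conditions, logical(1), gates = gates)
  list(hole_mask = holes, bronchi = recs[pass])
}

#' Rasterise component records into a logical mask
#'
#' @param records list of [component_record()]s.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return logical matrix with the union of the records' pixel sets.
#' @export
records_to_mask <- function(records, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  for (r in records) m[r$pixels] <- TRUE
  m
}

#' Match bronchi with arteries into BA pairs
#'
#' Every screened bronchus hole is paired with the nearest (centroid
#' distance) potential artery that overlaps the bronchus's host contour;
#' ties break towards the smaller artery label. Hosts carrying no
#' (bronchus, artery) match produce no pair. Matches whose bronchus and
#' artery centroids are farther apart than `max_dist` are rejected as
#' implausible. The pair coordinate is the rounded midpoint of the two
#' centroids; the lung side is read from the lung-mask component containing
#' the coordinate (by default image-left is the patient's right lung, the
#' radiological convention; set `flip_sides` to invert). When several
#' bronchi share one artery the pairs are flagged non-discrete.
#'
#' @param arteries result of [detect_potential_arteries()].
#' @param bronchi list of bronchus [component_record()]s from
#'   [detect_potential_bronchi()].
#' @param hosts host contours from [extract_adjacent_objects()].
#' @param lung_mask logical lung mask for side assignment.
#' @param slice_no integer slice number stored in each record.
#' @param max_dist maximum bronchus-artery centroid distance in px.
#' @param flip_sides invert the left/right convention.
#' @return list of BA pair records: `pair_id`, `slice_no`, `x`, `y`,
#'   `lung_side`, `discrete`, plus the `bronchus`, `artery` and `host`
#'   component records.
#' @export
extract_ba_pairs <- function(arteries, bronchi, hosts, lung_mask,
                             slice_no = 1L, max_dist = 40, flip_sides = FALSE) {
  if (!length(bronchi) || !length(hosts) || !length(arteries$kept))
    return(list())
  dims <- dim(lung_mask)
  host_lab <- matrix(0L, dims[1], dims[2])
  for (i in seq_along(hosts)) host_lab[hosts[[i]]$pixels] <- i

  lung_lab <- label_components(lung_mask)
  lung_side_of <- function(xy) {
    l <- 0L
    r0 <- min(max(xy[2], 1L), dims[1]); c0 <- min(max(xy[1], 1L), dims[2])
    l <- lung_lab[r0, c0]
    if (l == 0L && any(lung_lab > 0L)) {   # nearest lung component
      idx <- which(lung_lab > 0L)
      rr <- ((idx - 1L) %% dims[1]) + 1L
      cc <- ((idx - 1L) %/% dims[1]) + 1L
      l <- lung_lab[idx[which.min((rr - r0)^2 + (cc - c0)^2)]]
    }
    if (l == 0L) return(NA_character_)
    cx <- mean(((which(lung_lab == l) - 1L) %/% dims[1]) + 1L)
    side <- if (cx <= dims[2] / 2) "right" else "left"
    if (flip_sides) side <- setdiff(c("left", "right"), side)
    side
  }

  pairs <- list()
  artery_use <- integer(length(arteries$kept))
  for (b in bronchi) {
    # host of this hole: the component its 1-px dilation touches
    nb <- .dilate1(b$pixels, dims)
    hl <- unique(host_lab[nb])
    hl <- hl[hl > 0L]
    if (!length(hl)) next
    host <- hosts[[hl[1]]]
    cand <- host$artery_labels
    if (!length(cand)) next
    dists <- vapply(cand, function(i) {
      a <- arteries$kept[[i]]
      sqrt(sum((a$centroid - b$centroid)^2))
    }, numeric(1))
    ord <- order(dists, cand)
    best <- cand[ord[1]]
    if (dists[ord[1]] > max_dist) next
    a <- arteries$kept[[best]]
    artery_use[best] <- artery_use[best] + 1L
    mid <- (a$centroid + b$centroid) / 2
    xy <- c(floor(mid[1] + 0.5), floor(mid[2] + 0.5))
    pairs[[length(pairs) + 1L]] <- list(
      pair_id = NA_integer_,
      slice_no = as.integer(slice_no),
      x = as.integer(xy[1]), y = as.integer(xy[2]),
      lung_side = lung_side_of(xy),
      discrete = TRUE,
      bronchus = b, artery = a, host = host,
      artery_index = best)
  }
  if (!length(pairs)) return(pairs)
  shared <- which(artery_use > 1L)
  for (i in seq_along(pairs)) {
    if (pairs[[i]]$artery_index %in% shared) pairs[[i]]$discrete <- FALSE
    pairs[[i]]$pair_id <- i
  }
  pairs
}

# 8-neighbourhood dilation of a pixel set, returned as (row, col) matrix
.dilate1 <- function(pix, dims) {
  off <- expand.grid(dr = -1:1, dc = -1:1)
  rr <- rep(pix[, 1], each = 9L) + off$dr
  cc <- rep(pix[, 2], each = 9L) + off$dc
  ok <- rr >= 1L & rr <= dims[1] & cc >= 1L & cc <= dims[2]
  unique(cbind(rr[ok], cc[ok]))
}
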