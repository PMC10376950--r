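#' Label connected components under 8-connectivity
#'
#' Run-based two-pass labelling with union-find. Pixels are foreground when
#' `> 0`. Labels are assigned in row-major order of first appearance, so the
#' numbering is deterministic and "smallest label" tie-breaks are
#' reproducible. 8-connectivity is used throughout the pipeline: two
#' foreground pixels belong to the same component when they touch edge- or
#' corner-wise.
#'
#' @param mask logical or numeric matrix; `> 0` is foreground.
#' @return integer matrix of the same shape; 0 is background, components are
#'   numbered `1..n`.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  fg <- mask > 0
  if (!any(fg)) return(lab)

  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(a, b) {
    ra <- find_root(a); rb <- find_root(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }

  nrun <- 0L
  run_row <- vector("list", h)
  run_s <- vector("list", h)
  run_e <- vector("list", h)
  run_id <- vector("list", h)
  prev_id <- integer(0); prev_s <- integer(0); prev_e <- integer(0)

  for (y in seq_len(h)) {
    r <- rle(fg[y, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cs <- starts[r$values]
    ce <- ends[r$values]
    ids <- integer(length(cs))
    if (length(cs)) {
      for (k in seq_along(cs)) {
        nrun <- nrun + 1L
        parent[nrun] <- nrun
        ids[k] <- nrun
        if (length(prev_id)) {
          ov <- which(prev_e >= cs[k] - 1L & prev_s <= ce[k] + 1L)
          for (j in ov) link(nrun, prev_id[j])
        }
      }
      run_row[[y]] <- rep.int(y, length(cs))
      run_s[[y]] <- cs
      run_e[[y]] <- ce
      run_id[[y]] <- ids
    }
    prev_id <- ids; prev_s <- cs; prev_e <- ce
  }

  roots <- vapply(seq_len(nrun), find_root, integer(1))
  relab <- match(roots, unique(roots))  # row-major first-appearance order
  rr <- unlist(run_row); ss <- unlist(run_s); ee <- unlist(run_e)
  ii <- relab[unlist(run_id)]
  for (i in seq_along(rr)) lab[rr[i], ss[i]:ee[i]] <- ii[i]
  lab
}

# linear (column-major) indices of pixels per label, as a named list
.pixels_by_label <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) return(list())
  split(idx, lab[idx])
}
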