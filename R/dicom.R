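#' Minimal DICOM slice reader
#'
#' Purpose-built reader for single-frame, uncompressed, little-endian CT
#' slices (explicit or implicit VR). It extracts only the technical tags the
#' pipeline needs — matrix size, bit depth, pixel representation, rescale
#' slope/intercept, window centre/width, instance number and the pixel
#' data — and ignores everything else, so patient-identifying metadata is
#' never propagated. Compressed transfer syntaxes and multi-frame or color
#' objects are rejected.
#'
#' @param path DICOM file path.
#' @return list with `pixels` (numeric matrix in rescaled units, e.g. HU),
#'   `window` (`c(center, width)` or `NULL`), `instance` (integer or `NA`).
#' @export
read_dicom <- function(path) {
  raw <- tryCatch(readBin(path, "raw", n = file.size(path)),
                  error = function(e) stop("cannot read DICOM ", path, ": ",
                                           conditionMessage(e)))
  off <- 0L
  if (length(raw) > 132L && rawToChar(raw[129:132]) == "DICM") off <- 132L
  n <- length(raw)
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) as.integer(raw[i]) + 256 * as.integer(raw[i + 1L]) +
    65536 * as.integer(raw[i + 2L]) + 16777216 * as.integer(raw[i + 3L])

  # explicit VR if the first element after the header carries a VR code;
  # the file-meta group (0002) is always explicit, the body follows the
  # transfer syntax
  probe <- if (n >= off + 6L) rawToChar(raw[(off + 5L):(off + 6L)]) else ""
  body_explicit <- grepl("^[A-Z][A-Z]$", probe)

  tags <- list()
  i <- off + 1L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (i + 7L <= n) {
    grp <- u16(i); el <- u16(i + 2L)
    key <- sprintf("%04x,%04x", grp, el)
    if (grp != 2L && !is.null(tags[["0002,0010"]])) {
      ts0 <- sub("\\s+$", "", rawToChar(tags[["0002,0010"]]))
      body_explicit <- !identical(ts0, "1.2.840.10008.1.2")
    }
    explicit <- if (grp == 2L) TRUE else body_explicit
    if (explicit && grp != 0xFFFE) {
      vr <- rawToChar(raw[(i + 4L):(i + 5L)])
      if (vr %in% long_vrs) {
        len <- u32(i + 8L); hdr <- 12L
      } else {
        len <- u16(i + 6L); hdr <- 8L
      }
    } else {
      vr <- ""
      len <- u32(i + 4L); hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements are not supported: ", path)
    vstart <- i + hdr
    if (vstart + len - 1L > n) break
    if (key %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0103",
                   "0028,1050", "0028,1051", "0028,1052", "0028,1053",
                   "0020,0013", "0028,0002", "0028,0008", "0002,0010",
                   "7fe0,0010")) {
      tags[[key]] <- raw[vstart:(vstart + len - 1L)]
    }
    i <- vstart + len
  }

  ts <- if (!is.null(tags[["0002,0010"]]))
    sub("\\s+$", "", rawToChar(tags[["0002,0010"]])) else NULL
  if (!is.null(ts) &&
      !ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop("unsupported (compressed or big-endian) transfer syntax in ", path)

  num_str <- function(key, default = NA_real_) {
    v <- tags[[key]]
    if (is.null(v)) return(default)
    s <- strsplit(sub("\\s+$", "", rawToChar(v)), "\\\\")[[1]][1]
    as.numeric(s)
  }
  u16_tag <- function(key, default = NA_integer_) {
    v <- tags[[key]]
    if (is.null(v) || length(v) < 2L) return(default)
    as.integer(v[1]) + 256L * as.integer(v[2])
  }

  rows <- u16_tag("0028,0010"); cols <- u16_tag("0028,0011")
  bits <- u16_tag("0028,0100", 16L)
  signed <- identical(u16_tag("0028,0103", 0L), 1L)
  spp <- u16_tag("0028,0002", 1L)
  frames <- num_str("0028,0008", 1)
  if (is.na(rows) || is.na(cols) || is.null(tags[["7fe0,0010"]]))
    stop("not a readable single-frame DICOM image: ", path)
  if (spp != 1L) stop("color DICOM input is not supported: ", path)
  if (!is.na(frames) && frames > 1) stop("multi-frame DICOM input is not supported: ", path)

  pd <- tags[["7fe0,0010"]]
  npx <- rows * cols
  if (bits == 8L) {
    v <- as.integer(pd[seq_len(npx)])
    if (signed) v <- ifelse(v > 127L, v - 256L, v)
  } else if (bits == 16L) {
    if (length(pd) < 2L * npx) stop("truncated pixel data in ", path)
    v <- readBin(pd, "integer", n = npx, size = 2L, signed = signed,
                 endian = "little")
  } else stop("unsupported bit depth (", bits, ") in ", path)

  slope <- num_str("0028,1053", 1); if (is.na(slope)) slope <- 1
  inter <- num_str("0028,1052", 0); if (is.na(inter)) inter <- 0
  px <- matrix(v * slope + inter, nrow = rows, ncol = cols, byrow = TRUE)

  wc <- num_str("0028,1050"); ww <- num_str("0028,1051")
  window <- if (!is.na(wc) && !is.na(ww)) c(wc, ww) else NULL
  inst <- suppressWarnings(as.integer(num_str("0020,0013")))
  list(pixels = px, window = window, instance = inst)
}
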