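# Write a minimal explicit-VR little-endian part-10 DICOM file for reader
# tests. Stored values are 16-bit (signed by default); modality rescale and
# window tags optional.
write_test_dicom <- function(path, stored, slope = 1, intercept = 0,
                             window_center = NULL, window_width = NULL,
                             instance = 1L, signed = TRUE) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  raw16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")
  str_raw <- function(s) {
    r <- charToRaw(as.character(s))
    if (length(r) %% 2) r <- c(r, charToRaw(" "))
    r
  }
  elem <- function(grp, el, vr, val) {
    w16(grp); w16(el)
    writeChar(vr, con, eos = NULL)
    if (vr %in% c("OB", "OW")) {
      w16(0)
      writeBin(length(val), con, size = 4, endian = "little")
    } else {
      w16(length(val))
    }
    writeBin(val, con)
  }
  elem(0x0002, 0x0010, "UI", str_raw("1.2.840.10008.1.2.1"))
  elem(0x0020, 0x0013, "IS", str_raw(instance))
  elem(0x0028, 0x0002, "US", raw16(1))
  elem(0x0028, 0x0010, "US", raw16(nrow(stored)))
  elem(0x0028, 0x0011, "US", raw16(ncol(stored)))
  elem(0x0028, 0x0100, "US", raw16(16))
  elem(0x0028, 0x0103, "US", raw16(if (signed) 1 else 0))
  if (!is.null(window_center)) {
    elem(0x0028, 0x1050, "DS", str_raw(window_center))
    elem(0x0028, 0x1051, "DS", str_raw(window_width))
  }
  elem(0x0028, 0x1052, "DS", str_raw(intercept))
  elem(0x0028, 0x1053, "DS", str_raw(slope))
  pd <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  elem(0x7FE0, 0x0010, "OW", pd)
  invisible(path)
}
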