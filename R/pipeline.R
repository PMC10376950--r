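#' Pipeline configuration
#'
#' All tunable thresholds of the per-slice pipeline with their defaults:
#' the artery gates (`10 <= area < 300`, circularity > 0.3, bounding-box
#' ratio > 0.4, enclosed-circle ratio > 0.4), the bronchus gates (area
#' > 3 px, circularity > 0.5, both ratios > 0.6), the histogram band count
#' for the NPT rule, the TV denoising weight, the alpha-beta target mean,
#' the output rounding mode, the left/right convention and the maximum
#' bronchus-artery pairing distance.
#'
#' @param artery named list from [condition_gates()].
#' @param bronchus named list from [condition_gates()].
#' @param n_bands histogram bands for the NPT rule.
#' @param tv_weight total-variation denoising weight.
#' @param ab_target,ab_tol alpha-beta correction target mean and no-op band.
#' @param min_lung_frac minimum lung area fraction; below it a slice is
#'   flagged "no-lung" and skipped.
#' @param max_pair_dist maximum bronchus-artery centroid distance, px.
#' @param flip_sides invert the radiological left/right convention.
#' @param rounding `"half_up"` or `"truncate"` for table output.
#' @param window optional DICOM window `c(center, width)`.
#' @param debug_dir optional directory for per-stage debug PNGs.
#' @return named list of class `"ba_config"`.
#' @export
pipeline_config <- function(artery = artery_gates(),
                            bronchus = bronchus_gates(),
                            n_bands = 3L, tv_weight = 0.1,
                            ab_target = 110, ab_tol = 15,
                            min_lung_frac = 0.01, max_pair_dist = 40,
                            flip_sides = FALSE,
                            rounding = c("half_up", "truncate"),
                            window = NULL, debug_dir = NULL) {
  structure(list(artery = artery, bronchus = bronchus,
                 n_bands = as.integer(n_bands), tv_weight = tv_weight,
                 ab_target = ab_target, ab_tol = ab_tol,
                 min_lung_frac = min_lung_frac,
                 max_pair_dist = max_pair_dist, flip_sides = flip_sides,
                 rounding = match.arg(rounding), window = window,
                 debug_dir = debug_dir),
            class = "ba_config")
}

#' Serialise / parse a flat key-value config file
#'
#' One `key = value` pair per line; gate thresholds use dotted keys
#' (`artery.area_min` etc.). Written alongside every run's outputs so the
#' exact thresholds are always recorded with the results.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_config()` returns a `"ba_config"`.
#' @export
write_config <- function(config, path) {
  flat <- c(
    setNames(unlist(config$artery), paste0("artery.", names(config$artery))),
    setNames(unlist(config$bronchus), paste0("bronchus.", names(config$bronchus))),
    n_bands = config$n_bands, tv_weight = config$tv_weight,
    ab_target = config$ab_target, ab_tol = config$ab_tol,
    min_lung_frac = config$min_lung_frac,
    max_pair_dist = config$max_pair_dist,
    flip_sides = as.integer(config$flip_sides))
  lines <- c(paste(names(flat), unname(flat), sep = " = "),
             paste0("rounding = ", config$rounding))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- grep("=", readLines(path), value = TRUE)
  kv <- do.call(rbind, strsplit(lines, "\\s*=\\s*"))
  vals <- setNames(as.list(kv[, 2]), kv[, 1])
  num <- function(k, d) if (!is.null(vals[[k]])) as.numeric(vals[[k]]) else d
  cfg <- pipeline_config()
  for (g in c("artery", "bronchus"))
    for (f in names(cfg[[g]]))
      cfg[[g]][[f]] <- num(paste0(g, ".", f), cfg[[g]][[f]])
  cfg$n_bands <- as.integer(num("n_bands", cfg$n_bands))
  cfg$tv_weight <- num("tv_weight", cfg$tv_weight)
  cfg$ab_target <- num("ab_target", cfg$ab_target)
  cfg$ab_tol <- num("ab_tol", cfg$ab_tol)
  cfg$min_lung_frac <- num("min_lung_frac", cfg$min_lung_frac)
  cfg$max_pair_dist <- num("max_pair_dist", cfg$max_pair_dist)
  cfg$flip_sides <- num("flip_sides", 0) > 0
  if (!is.null(vals[["rounding"]])) cfg$rounding <- vals[["rounding"]]
  cfg
}

#' Run the full BA pipeline on one slice
#'
#' Chains [segment_lungs()], [clean_image()],
#' [detect_potential_arteries()], [extract_adjacent_objects()],
#' [detect_potential_bronchi()], [extract_ba_pairs()] and [measure_pair()],
#' attaching the measurement to every pair record.
#'
#' @param img gray-image matrix.
#' @param config a [pipeline_config()].
#' @param slice_no integer slice id recorded in the pair records.
#' @return list with `pairs` (measured BA pair records), `lung`
#'   ([segment_lungs()] result), `thresholds` (histogram-cleaning
#'   thresholds or `NULL`), `arteries`, `hosts`, `bronchi`, and `no_lung`.
#' @export
process_slice <- function(img, config = pipeline_config(), slice_no = 1L) {
  empty <- list(pairs = list(), lung = NULL, thresholds = NULL,
                arteries = NULL, hosts = list(), bronchi = list(),
                no_lung = TRUE)
  lung <- segment_lungs(img, config)
  empty$lung <- lung
  if (lung$no_lung) return(empty)
  cl <- clean_image(lung$lung_img, n_bands = config$n_bands)
  empty$thresholds <- cl$thresholds
  if (!any(cl$clean_img > 0)) return(empty)
  art <- detect_potential_arteries(cl$clean_img, gates = config$artery)
  empty$arteries <- art
  hosts <- extract_adjacent_objects(art$updated_clean, art)
  empty$hosts <- hosts
  if (!length(hosts)) { empty$no_lung <- FALSE; return(empty) }
  host_mask <- records_to_mask(hosts, dim(img))
  br <- detect_potential_bronchi(host_mask, gates = config$bronchus)
  empty$bronchi <- br$bronchi
  pairs <- extract_ba_pairs(art, br$bronchi, hosts, lung$lung_mask,
                            slice_no = slice_no,
                            max_dist = config$max_pair_dist,
                            flip_sides = config$flip_sides)
  pairs <- Filter(function(p) {
    m <- tryCatch(measure_pair(p$bronchus, p$artery), error = function(e) {
      warning("measurement failed for a pair on slice ", slice_no, ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    !is.null(m)
  }, pairs)
  pairs <- lapply(pairs, function(p) {
    p$measurement <- measure_pair(p$bronchus, p$artery)
    p
  })
  list(pairs = pairs, lung = lung, thresholds = cl$thresholds,
       arteries = art, hosts = hosts, bronchi = br$bronchi,
       no_lung = FALSE)
}

#' Run the pipeline over a slice stack and write run artifacts
#'
#' Slices are processed independently (no cross-slice state), so results do
#' not depend on processing order and repeated runs are byte-identical.
#' Outputs written under `out_dir`: `pairs.csv` (pair table with
#' measurements), `summary.csv` (per-lung pair counts and ratio
#' aggregates), `thresholds.csv` (per-slice histogram-cleaning log),
#' `config.txt` (snapshot), and one `overlay_<slice>.png` per slice with
#' detected pairs (bronchi red, arteries blue).
#'
#' @param input a [slice_stack()], a list of gray-image matrices, or a
#'   directory path (read with [read_slice_stack()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing.
#' @param format input format when `input` is a directory.
#' @return invisible list with `pairs` (all measured pair records),
#'   `summary` (from [summarize_patient()]), `table` (the pair data frame)
#'   and `per_slice` results.
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         format = c("png", "dicom")) {
  format <- match.arg(format)
  if (is.character(input)) {
    input <- read_slice_stack(input, format = format, window = config$window)
  } else if (is.list(input) && !inherits(input, "slice_stack")) {
    input <- slice_stack(input)
  }
  if (!length(input$slices)) stop("empty input: no slices to process")

  per_slice <- vector("list", length(input$slices))
  all_pairs <- list()
  thr_log <- NULL
  for (i in seq_along(input$slices)) {
    sid <- input$slice_ids[i]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(process_slice(input$slices[[i]], config, slice_no = sid),
                    error = function(e) {
                      warning("slice ", sid, " failed: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    per_slice[[i]] <- res
    if (is.null(res)) next
    ms <- round((proc.time()[["elapsed"]] - t0) * 1000)
    message(sprintf("slice=%d stage=pipeline pairs=%d hosts=%d ms=%d",
                    sid, length(res$pairs), length(res$hosts), ms))
    all_pairs <- c(all_pairs, res$pairs)
    if (!is.null(res$thresholds))
      thr_log <- rbind(thr_log, data.frame(
        slice_no = sid, HPI = res$thresholds$HPI,
        peak_height = res$thresholds$peak_height,
        NPT = res$thresholds$NPT, PIT = res$thresholds$PIT))
  }

  measurements <- lapply(all_pairs, `[[`, "measurement")
  summ <- summarize_patient(measurements, all_pairs)
  tab <- pairs_to_table(all_pairs, rounding = config$rounding)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_pair_table(all_pairs, file.path(out_dir, "pairs.csv"),
                     rounding = config$rounding)
    sdf <- data.frame(n_pairs = summ$n_pairs, n_right = summ$n_right,
                      n_left = summ$n_left,
                      BADR_mean = summ$BADR["mean"] %||% NA,
                      BADR_min = summ$BADR["min"] %||% NA,
                      BADR_max = summ$BADR["max"] %||% NA,
                      BAAR_mean = summ$BAAR["mean"] %||% NA,
                      BAAR_min = summ$BAAR["min"] %||% NA,
                      BAAR_max = summ$BAAR["max"] %||% NA)
    write.csv(sdf, file.path(out_dir, "summary.csv"), row.names = FALSE)
    if (!is.null(thr_log))
      write.csv(thr_log, file.path(out_dir, "thresholds.csv"),
                row.names = FALSE)
    write_config(config, file.path(out_dir, "config.txt"))
    for (i in seq_along(input$slices)) {
      res <- per_slice[[i]]
      if (is.null(res)) next
      pm <- pair_mask(res$pairs, dim(input$slices[[i]]))
      write_overlay(input$slices[[i]], pm,
                    file.path(out_dir, sprintf("overlay_%04d.png",
                                               input$slice_ids[i])))
    }
  }
  invisible(list(pairs = all_pairs, summary = summ, table = tab,
                 per_slice = per_slice))
}
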