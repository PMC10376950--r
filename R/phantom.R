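#' Specification of a synthetic axial-slice phantom
#'
#' The phantom emulates the features the pipeline keys on: a dark
#' background, a brighter body ellipse, two dark elliptical lung fields,
#' bright near-circular artery disks, adjacent "signet-ring" bronchi (a
#' bright annular wall around a dark lumen at parenchyma intensity),
#' elongated bright bars (in-plane vessels acting as distractors), lone
#' rings without an accompanying artery, low-intensity speckle, and
#' additive Gaussian noise. Every planted object is recorded with its
#' ground-truth geometry so detections can be scored.
#'
#' Intensity palette defaults: background 0, body 170, lung parenchyma 35,
#' vessel/artery 225, bronchial wall 100, lumen 35. The wall sits between
#' the histogram-cleaning threshold (just above parenchyma) and the
#' balanced-histogram threshold (between wall and vessel), reproducing the
#' appearance the method expects: walls survive cleaning but only vessels
#' count as "bright".
#'
#' @param seed integer RNG seed; generation is fully determined by it.
#' @param n_pairs number of planted BA pairs.
#' @param lumen_radius_range,artery_radius_range integer radius ranges, px.
#' @param wall_thickness bronchial wall thickness, px.
#' @param n_distractor_vessels number of elongated bright bars.
#' @param n_lone_rings number of rings without an adjacent artery.
#' @param n_speckle number of small low-intensity speckle clusters.
#' @param noise_sigma Gaussian noise standard deviation in intensity units.
#' @param intensities named list overriding palette entries (`background`,
#'   `body`, `lung`, `vessel`, `wall`, `lumen`).
#' @return object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(seed = 1L, n_pairs = 3L,
                         lumen_radius_range = c(3L, 6L),
                         artery_radius_range = c(5L, 9L),
                         wall_thickness = 3L,
                         n_distractor_vessels = 4L, n_lone_rings = 1L,
                         n_speckle = 40L, noise_sigma = 6,
                         intensities = list()) {
  pal <- modifyList(list(background = 0, body = 170, lung = 35,
                         vessel = 225, wall = 100, lumen = 35),
                    intensities)
  stopifnot(lumen_radius_range[1] >= 2, artery_radius_range[1] >= 2,
            all(unlist(pal) >= 0), all(unlist(pal) <= 255))
  if (pal$vessel < pal$lung + 60 || pal$wall < pal$lung + 60)
    stop("vessel and wall intensities must exceed lung intensity by >= 60")
  structure(list(seed = as.integer(seed), n_pairs = as.integer(n_pairs),
                 lumen_radius_range = as.integer(lumen_radius_range),
                 artery_radius_range = as.integer(artery_radius_range),
                 wall_thickness = as.integer(wall_thickness),
                 n_distractor_vessels = as.integer(n_distractor_vessels),
                 n_lone_rings = as.integer(n_lone_rings),
                 n_speckle = as.integer(n_speckle),
                 noise_sigma = noise_sigma, intensities = pal),
            class = "phantom_spec")
}

# run code with a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one phantom slice with ground truth
#'
#' Objects are placed by rejection sampling inside the lung ellipses with a
#' minimum clearance between objects; generation fails (with an error)
#' after 1000 rejected attempts, which signals an over-full specification.
#' The artery of each pair is planted tangent to its bronchus wall
#' (centre distance `r_wall_outer + r_artery - 1` px) so the pair forms one
#' connected structure, as discrete BA pairs do on CT.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (512x512 gray matrix) and `truth` (list:
#'   `lung_mask`, `pairs` data frame with bronchus/artery centres, radii
#'   and `true_BADR = r_lumen / r_artery`, `distractors` inventory).
#' @export
generate_slice <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, .generate_slice_impl(spec))
}

.generate_slice_impl <- function(spec) {
  size <- 512L
  pal <- spec$intensities
  img <- matrix(pal$background, size, size)
  cc <- col(img); rr <- row(img)

  in_ellipse <- function(cx, cy, a, b) {
    ((cc - cx) / a)^2 + ((rr - cy) / b)^2 <= 1
  }
  body <- in_ellipse(256, 260, 205, 175)
  img[body] <- pal$body
  lungs <- list(c(cx = 158, cy = 265, a = 75, b = 125),
                c(cx = 354, cy = 265, a = 75, b = 125))
  lung_mask <- matrix(FALSE, size, size)
  for (L in lungs) {
    m <- in_ellipse(L["cx"], L["cy"], L["a"], L["b"])
    img[m] <- pal$lung
    lung_mask <- lung_mask | m
  }

  placed_x <- numeric(0); placed_y <- numeric(0); placed_r <- numeric(0)
  attempts <- 0L
  place <- function(obj_r, clearance = 4) {
    repeat {
      attempts <<- attempts + 1L
      if (attempts > 1000L)
        stop("phantom generation failed: objects do not fit without overlap")
      L <- lungs[[sample.int(2L, 1L)]]
      th <- runif(1, 0, 2 * pi)
      u <- sqrt(runif(1))
      margin_a <- max(L["a"] - obj_r - 3, 1)
      margin_b <- max(L["b"] - obj_r - 3, 1)
      x <- L["cx"] + u * margin_a * cos(th)
      y <- L["cy"] + u * margin_b * sin(th)
      # fully inside the lung ellipse?
      if (((x - L["cx"]) / (L["a"] - obj_r - 2))^2 +
          ((y - L["cy"]) / (L["b"] - obj_r - 2))^2 > 1) next
      if (length(placed_x)) {
        d <- sqrt((placed_x - x)^2 + (placed_y - y)^2)
        if (any(d < placed_r + obj_r + clearance)) next
      }
      placed_x <<- c(placed_x, x); placed_y <<- c(placed_y, y)
      placed_r <<- c(placed_r, obj_r)
      return(c(x = as.numeric(x), y = as.numeric(y)))
    }
  }
  disk <- function(x, y, r) (cc - x)^2 + (rr - y)^2 <= r^2

  # BA pairs
  pairs <- NULL
  for (k in seq_len(spec$n_pairs)) {
    r_l <- sample(spec$lumen_radius_range[1]:spec$lumen_radius_range[2], 1L)
    r_a <- sample(spec$artery_radius_range[1]:spec$artery_radius_range[2], 1L)
    r_o <- r_l + spec$wall_thickness
    ext <- r_o + 2 * r_a          # pair bounding radius around the bronchus
    ctr <- place(ext)
    phi <- runif(1, 0, 2 * pi)
    d <- r_o + r_a - 1            # tangent with 1 px overlap
    ax <- ctr["x"] + d * cos(phi)
    ay <- ctr["y"] + d * sin(phi)
    img[disk(ctr["x"], ctr["y"], r_o)] <- pal$wall
    img[disk(ctr["x"], ctr["y"], r_l)] <- pal$lumen
    img[disk(ax, ay, r_a)] <- pal$vessel
    pairs <- rbind(pairs, data.frame(
      bronchus_x = ctr["x"], bronchus_y = ctr["y"], lumen_radius = r_l,
      wall_outer_radius = r_o, artery_x = as.numeric(ax),
      artery_y = as.numeric(ay), artery_radius = r_a,
      true_BADR = r_l / r_a, row.names = NULL))
  }

  # elongated distractor vessels (bars)
  bars <- NULL
  for (k in seq_len(spec$n_distractor_vessels)) {
    len <- runif(1, 40, 60)
    ctr <- place(len / 2 + 2)
    th <- runif(1, 0, pi)
    u <- c(cos(th), sin(th))
    proj <- (cc - ctr["x"]) * u[1] + (rr - ctr["y"]) * u[2]
    perp <- -(cc - ctr["x"]) * u[2] + (rr - ctr["y"]) * u[1]
    img[abs(proj) <= len / 2 & abs(perp) <= 1.5] <- pal$vessel
    bars <- rbind(bars, data.frame(x = ctr["x"], y = ctr["y"],
                                   length = len, angle = th,
                                   row.names = NULL))
  }

  # lone rings (bronchus without adjacent artery)
  rings <- NULL
  for (k in seq_len(spec$n_lone_rings)) {
    r_l <- sample(spec$lumen_radius_range[1]:spec$lumen_radius_range[2], 1L)
    r_o <- r_l + spec$wall_thickness
    ctr <- place(r_o)
    img[disk(ctr["x"], ctr["y"], r_o)] <- pal$wall
    img[disk(ctr["x"], ctr["y"], r_l)] <- pal$lumen
    rings <- rbind(rings, data.frame(x = ctr["x"], y = ctr["y"],
                                     lumen_radius = r_l, row.names = NULL))
  }

  # low-intensity speckle clusters (cleaned away by the PIT stage)
  for (k in seq_len(spec$n_speckle)) {
    ctr <- place(2, clearance = 6)
    x0 <- round(ctr["x"]); y0 <- round(ctr["y"])
    np <- sample.int(4L, 1L)
    for (j in seq_len(np)) {
      xo <- x0 + sample(-1:1, 1L); yo <- y0 + sample(-1:1, 1L)
      if (xo >= 1 && xo <= size && yo >= 1 && yo <= size && lung_mask[yo, xo])
        img[yo, xo] <- pal$lung + sample(3:6, 1L)
    }
  }

  if (spec$noise_sigma > 0)
    img <- img + rnorm(length(img), 0, spec$noise_sigma)

  list(image = as_gray_image(img),
       truth = list(lung_mask = lung_mask, pairs = pairs,
                    distractors = list(bars = bars, lone_rings = rings)))
}

#' Score detected pairs against phantom ground truth
#'
#' A detected pair matches a planted pair when its bronchus centroid lies
#' within `tol` px of the planted bronchus centre and its artery centroid
#' within `tol` px of the planted artery centre; matching is one-to-one
#' (greedy, nearest first). Recall is matched/planted and precision
#' matched/detected; with zero detections precision is reported as 1.0
#' (vacuously, flagged by `no_detections`). `ratio_MAE` is the mean
#' absolute error of the measured diameter ratio against
#' `true_BADR = r_lumen / r_artery` over the matches.
#'
#' @param truth the `truth` element of [generate_slice()].
#' @param pairs detected BA pair records with attached `measurement`s.
#' @param tol matching tolerance in px (default 5).
#' @return list with `recall`, `precision`, `ratio_MAE`, `n_matched`,
#'   `no_detections`, and `ratio_errors` (per-match absolute errors).
#' @export
score_detection <- function(truth, pairs, tol = 5) {
  planted <- truth$pairs
  n_true <- if (is.null(planted)) 0L else nrow(planted)
  n_det <- length(pairs)
  if (n_det == 0L) {
    return(list(recall = if (n_true > 0) 0 else 1,
                precision = 1.0, ratio_MAE = NA_real_,
                n_matched = 0L, no_detections = TRUE,
                ratio_errors = numeric(0)))
  }
  used <- logical(n_true)
  errs <- numeric(0)
  matched <- 0L
  for (p in pairs) {
    if (!n_true) break
    db <- sqrt((planted$bronchus_x - p$bronchus$centroid["x"])^2 +
                 (planted$bronchus_y - p$bronchus$centroid["y"])^2)
    da <- sqrt((planted$artery_x - p$artery$centroid["x"])^2 +
                 (planted$artery_y - p$artery$centroid["y"])^2)
    ok <- which(!used & db <= tol & da <= tol)
    if (!length(ok)) next
    j <- ok[which.min(db[ok] + da[ok])]
    used[j] <- TRUE
    matched <- matched + 1L
    if (!is.null(p$measurement))
      errs <- c(errs, abs(p$measurement$BADR - planted$true_BADR[j]))
  }
  list(recall = if (n_true > 0) matched / n_true else 1,
       precision = matched / n_det,
       ratio_MAE = if (length(errs)) mean(errs) else NA_real_,
       n_matched = matched, no_detections = FALSE,
       ratio_errors = errs)
}
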