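#' Whole-skeleton segmentation configuration
#'
#' Parameters of the semi-automatic skeleton segmentation. Defaults are the
#' published pipeline settings: bone window W 1800 / L 400 HU, fixed 120 HU
#' initial threshold, active-contour weights `mu = lambda1 = lambda2 = 1`,
#' and two initial contour iterations.
#'
#' @param window_width,window_level bone display window in HU.
#' @param threshold initial-contour threshold in HU, applied to the raw
#'   weighted-average image with a closed (>=) comparison; must exceed 100.
#' @param mu boundary-length penalty, realized as the number of alternating
#'   morphological smoothing rounds per iteration.
#' @param lambda1,lambda2 inner/outer region weights of the contour energy.
#' @param initial_iterations contour iterations run by [segment_skeleton()].
#' @param extra_fill_slices integer slice indices whose 2-D cross-sections
#'   get internal holes filled during refinement (the radiologist-in-the-loop
#'   step for long-bone marrow); default none, fully automatic.
#' @param prosthesis_cap HU above which voxels (plus one dilation ring) are
#'   removed as metal; default 3000.
#' @param refine_floor HU below which mask voxels are removed during
#'   refinement as non-skeletal soft tissue (the low side of the "further HU
#'   thresholding" cleanup); the skeleton threshold search domain lies above
#'   100 HU, so the default floor is 100. Voxels added by the explicit
#'   slice-fill step are exempt, since that manual step exists to retain
#'   fatty (low-HU) long-bone marrow. Set to `-Inf` to disable.
#' @param strict if `TRUE`, degenerate contour states (empty inside or
#'   outside region) raise an error instead of returning unchanged with a
#'   warning.
#' @export
segmentation_config <- function(window_width = 1800, window_level = 400,
                                threshold = 120, mu = 1, lambda1 = 1,
                                lambda2 = 1, initial_iterations = 2,
                                extra_fill_slices = integer(),
                                prosthesis_cap = 3000, refine_floor = 100,
                                strict = FALSE) {
  if (window_width <= 0) stop("window_width must be positive")
  if (threshold <= 100) stop("threshold must exceed 100 HU")
  if (mu <= 0 || lambda1 <= 0 || lambda2 <= 0)
    stop("mu, lambda1 and lambda2 must be positive")
  structure(list(window_width = window_width, window_level = window_level,
                 threshold = threshold, mu = mu, lambda1 = lambda1,
                 lambda2 = lambda2, initial_iterations = initial_iterations,
                 extra_fill_slices = as.integer(extra_fill_slices),
                 prosthesis_cap = prosthesis_cap,
                 refine_floor = refine_floor, strict = strict),
            class = "segmentation_config")
}

#' Bone-window clipping and median normalization
#'
#' Clips the weighted-average HU to the bone display window
#' `[level - width/2, level + width/2]`, subtracts the volume's median
#' clipped value, and rescales affinely to `[0, 1]`. Monotone and
#' order-preserving; the contour energy operates on this normalized image
#' while the initial threshold stays on raw HU.
#'
#' Normalization "with the median" is implemented as median subtraction
#' (before an affine rescale) rather than division, because HU medians can be
#' zero or negative.
#'
#' @param img a `weighted_average_volume` or a numeric array of HU.
#' @param cfg a [segmentation_config()].
#' @return numeric array in `[0, 1]`, same shape.
#' @export
window_and_normalize <- function(img, cfg = segmentation_config()) {
  v <- if (inherits(img, "weighted_average_volume")) img$values else img
  lo <- cfg$window_level - cfg$window_width / 2
  hi <- cfg$window_level + cfg$window_width / 2
  v <- pmin(pmax(v, lo), hi)
  v <- v - stats::median(v)
  rng <- range(v)
  if (rng[2] - rng[1] <= 0)
    stop("degenerate normalization: constant volume")
  array((v - rng[1]) / (rng[2] - rng[1]), dim(v))
}

#' Fixed-threshold initial contour
#'
#' A voxel enters the initial mask iff its raw weighted-average HU is greater
#' than or equal to `threshold` (closed comparison, so the printed 120 HU is
#' itself included).
#'
#' @param img a `weighted_average_volume` or numeric HU array.
#' @param threshold HU.
#' @return logical array.
#' @export
initial_contour <- function(img, threshold = 120) {
  v <- if (inherits(img, "weighted_average_volume")) img$values else img
  m <- v >= threshold
  if (!any(m)) warning("initial contour is empty at this threshold")
  m
}

#' State of the morphological active contour
#'
#' @param mask logical array, the current contour region C.
#' @param iteration iteration counter.
#' @return object of class `acwe_state` with fitted region means `c1`
#'   (inside) and `c2` (outside) set to `NA` until the first step.
#' @export
acwe_state <- function(mask, iteration = 0L) {
  structure(list(mask = mask, c1 = NA_real_, c2 = NA_real_,
                 iteration = as.integer(iteration), degenerate = FALSE),
            class = "acwe_state")
}

#' One morphological active-contour iteration
#'
#' Minimizes the two-phase piecewise-constant contour energy
#' `mu*Length(C) + lambda1*Int_inside (I - c1)^2 + lambda2*Int_outside (I - c2)^2`
#' with morphological operators: (a) refit the region means `c1`, `c2`;
#' (b) on the morphological-gradient zone of the mask, move voxels inside
#' where `lambda1*(I - c1)^2 - lambda2*(I - c2)^2 < 0` and outside where it
#' is `> 0` (exact ties leave the voxel untouched); (c) apply `mu` rounds of
#' the alternating sup-inf / inf-sup smoothing pair, the morphological
#' realization of the length penalty.
#'
#' If either region is empty the state is returned unchanged with a warning
#' (`degenerate` flag set), or an error is raised when `cfg$strict`.
#'
#' @param img normalized image array (see [window_and_normalize()]).
#' @param state an [acwe_state()].
#' @param cfg a [segmentation_config()].
#' @return updated `acwe_state`.
#' @export
acwe_step <- function(img, state, cfg = segmentation_config()) {
  stopifnot(inherits(state, "acwe_state"))
  mask <- state$mask
  n_in <- sum(mask)
  if (n_in == 0L || n_in == length(mask)) {
    if (cfg$strict) stop("degenerate contour: empty inside or outside region")
    warning("degenerate contour region; state returned unchanged")
    state$degenerate <- TRUE
    return(state)
  }
  c1 <- mean(img[mask])
  c2 <- mean(img[!mask])
  zone <- dilate26(mask) & !erode26(mask)
  force_term <- cfg$lambda1 * (img[zone] - c1)^2 -
    cfg$lambda2 * (img[zone] - c2)^2
  zmask <- mask[zone]
  zmask[force_term < 0] <- TRUE
  zmask[force_term > 0] <- FALSE
  mask[zone] <- zmask
  for (r in seq_len(round(cfg$mu)))
    mask <- curvature_smooth(mask, state$iteration * round(cfg$mu) + r)
  structure(list(mask = mask, c1 = c1, c2 = c2,
                 iteration = state$iteration + 1L, degenerate = FALSE),
            class = "acwe_state")
}

#' Run several active-contour iterations
#'
#' @param img normalized image array.
#' @param mask logical array, the initial contour.
#' @param n_iter number of iterations, >= 1.
#' @param cfg a [segmentation_config()].
#' @return final `acwe_state`.
#' @export
run_acwe <- function(img, mask, n_iter = 2, cfg = segmentation_config()) {
  if (n_iter < 1) stop("n_iter must be at least 1")
  state <- acwe_state(mask)
  for (i in seq_len(n_iter)) state <- acwe_step(img, state, cfg)
  state
}

#' Rule-based mask refinement
#'
#' The manual-rule stage of the pipeline: (a) fills internal 2-D holes of the
#' mask on each listed slice (capturing long-bone marrow cavities); (b)
#' removes voxels whose raw HU exceeds `prosthesis_cap`, plus one dilation
#' ring around them (metal implants); (c) removes non-filled mask voxels with
#' raw HU below `refine_floor` (soft-tissue/CSF rims annexed by the contour
#' smoothing); (d) deletes voxels inside optional crop boxes. Provenance is
#' tracked per voxel.
#'
#' @param state an [acwe_state()] (or a logical array).
#' @param raw a `weighted_average_volume` or raw HU array.
#' @param cfg a [segmentation_config()].
#' @param crop_boxes optional list of boxes, each a list with integer ranges
#'   `x`, `y`, `z`; mask voxels inside any box are deleted.
#' @param provenance optional character array of per-voxel tags carried in.
#' @return a `skeleton_mask` object: list with logical `mask`, character
#'   `provenance` array (tags `threshold`, `acwe`, `fill`, `removed`, empty
#'   for background) and `voxel_count`.
#' @export
refine_mask <- function(state, raw, cfg = segmentation_config(),
                        crop_boxes = list(), provenance = NULL) {
  mask <- if (inherits(state, "acwe_state")) state$mask else state
  v <- if (inherits(raw, "weighted_average_volume")) raw$values else raw
  if (is.null(provenance)) {
    provenance <- array("", dim(mask))
    provenance[mask] <- "acwe"
  }
  for (s in cfg$extra_fill_slices) {
    if (s < 1 || s > dim(mask)[3])
      stop(sprintf("fill slice %d outside the volume", s))
    before <- mask
    mask <- fill_slice_holes(mask, s)
    provenance[mask & !before] <- "fill"
  }
  metal <- v > cfg$prosthesis_cap
  if (any(metal)) {
    metal <- dilate26(metal)
    provenance[mask & metal] <- "removed"
    mask <- mask & !metal
  }
  if (is.finite(cfg$refine_floor)) {
    low <- mask & v < cfg$refine_floor & provenance != "fill"
    provenance[low] <- "removed"
    mask <- mask & !low
  }
  for (b in crop_boxes) {
    sub <- array(FALSE, dim(mask))
    sub[b$x, b$y, b$z] <- TRUE
    provenance[mask & sub] <- "removed"
    mask <- mask & !sub
  }
  structure(list(mask = mask, provenance = provenance,
                 voxel_count = sum(mask)),
            class = "skeleton_mask")
}

#' @export
print.skeleton_mask <- function(x, ...) {
  cat(sprintf("skeleton_mask: %d voxels set of %s\n", x$voxel_count,
              paste(dim(x$mask), collapse = "x")))
  invisible(x)
}

#' End-to-end whole-skeleton segmentation
#'
#' The full published pipeline: 50:50 weighted average, bone-window
#' normalization, fixed 120 HU initial contour on raw HU, `initial_iterations`
#' morphological active-contour iterations on the normalized image, then
#' rule-based refinement. Randomness-free: identical inputs give identical
#' masks.
#'
#' @param vol a [dual_energy_volume()].
#' @param cfg a [segmentation_config()].
#' @param crop_boxes passed to [refine_mask()].
#' @return a `skeleton_mask`.
#' @export
segment_skeleton <- function(vol, cfg = segmentation_config(),
                             crop_boxes = list()) {
  wa <- weighted_average(vol, 0.5)
  norm <- window_and_normalize(wa, cfg)
  m0 <- initial_contour(wa, cfg$threshold)
  provenance <- array("", dim(m0))
  provenance[m0] <- "threshold"
  state <- run_acwe(norm, m0, cfg$initial_iterations, cfg)
  provenance[state$mask & provenance == ""] <- "acwe"
  provenance[!state$mask & provenance == "threshold"] <- ""
  refine_mask(state, wa, cfg, crop_boxes, provenance)
}

#' Dice overlap coefficient of two binary masks
#'
#' @param a,b logical arrays of the same shape.
#' @return `2|A n B| / (|A| + |B|)`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
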