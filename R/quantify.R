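#' First-order histogram summary of masked VNCa voxels
#'
#' The per-subject whole-skeleton summary: arithmetic mean, median (middle
#' order statistic; mean of the two middles for even n), sample SD (n - 1
#' denominator), skewness `g1 = m3 / m2^1.5` and excess kurtosis
#' `g2 = m4 / m2^2 - 3`, where `m_k` are central moments with the 1/n
#' convention. Skewness needs at least 3 voxels and kurtosis at least 4;
#' with constant values both are flagged undefined (`NA`).
#'
#' @param map a `vnca_map` (or numeric array).
#' @param mask a `skeleton_mask` (or logical array).
#' @param excess if `FALSE`, report raw kurtosis `m4 / m2^2` instead of
#'   excess.
#' @return object of class `histogram_summary`: list with `mean`, `median`,
#'   `sd`, `skewness`, `kurtosis`, `n_voxels`.
#' @examples
#' m <- array(c(-96, -96, 51.5, 0), c(2, 2, 1))
#' histogram_summary(m, array(c(TRUE, TRUE, TRUE, FALSE), c(2, 2, 1)))
#' @export
histogram_summary <- function(map, mask, excess = TRUE) {
  v <- if (inherits(map, "vnca_map")) map$values else map
  m <- if (inherits(mask, "skeleton_mask")) mask$mask else mask
  stopifnot(identical(dim(v), dim(m)))
  x <- v[m]
  n <- length(x)
  if (n == 0L) stop("empty selection: mask contains no voxels")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  constant <- m2 <= 0
  skew <- if (n < 3L || constant) NA_real_ else m3 / m2^1.5
  kurt <- if (n < 4L || constant) NA_real_
          else m4 / m2^2 - if (excess) 3 else 0
  structure(list(mean = mu, median = stats::median(x),
                 sd = if (n > 1L) stats::sd(x) else 0,
                 skewness = skew, kurtosis = kurt, n_voxels = n),
            class = "histogram_summary")
}

#' @export
print.histogram_summary <- function(x, ...) {
  cat(sprintf(
    "histogram_summary (n = %d voxels)\n  mean %.1f  median %.1f  sd %.1f  skewness %.2f  kurtosis %.2f\n",
    x$n_voxels, x$mean, x$median, x$sd, x$skewness, x$kurtosis))
  invisible(x)
}

#' Circular region-of-interest specification
#'
#' @param center in-plane voxel coordinates `(x, y)`, 1-based.
#' @param radius_mm circle radius in mm.
#' @param plane axial slice index.
#' @param kind `"regional"` (vertebral / iliac analog) or `"lesion"`.
#' @param label free-text anatomical label, metadata only.
#' @export
roi_spec <- function(center, radius_mm, plane,
                     kind = c("regional", "lesion"), label = "") {
  kind <- match.arg(kind)
  if (radius_mm <= 0) stop("radius_mm must be positive")
  structure(list(center = as.numeric(center), radius_mm = radius_mm,
                 plane = as.integer(plane), kind = kind, label = label),
            class = "roi_spec")
}

#' Rasterize a circular ROI
#'
#' A voxel belongs to the ROI iff its in-plane centre lies within
#' `radius_mm` of the ROI centre on the given slice (voxel-centre-in-circle
#' rule, no partial-volume weighting).
#'
#' @param spec a [roi_spec()].
#' @param dim grid size `(x, y, slices)`.
#' @param spacing mm per axis.
#' @return logical array of shape `dim`.
#' @export
roi_mask <- function(spec, dim, spacing) {
  stopifnot(inherits(spec, "roi_spec"))
  rx <- spec$radius_mm / spacing[1]
  ry <- spec$radius_mm / spacing[2]
  if (spec$plane < 1 || spec$plane > dim[3] ||
      spec$center[1] - rx < 1 || spec$center[1] + rx > dim[1] ||
      spec$center[2] - ry < 1 || spec$center[2] + ry > dim[2])
    stop("ROI circle extends outside the volume")
  x <- seq_len(dim[1]); y <- seq_len(dim[2])
  d2 <- outer(((x - spec$center[1]) * spacing[1])^2,
              ((y - spec$center[2]) * spacing[2])^2, "+")
  m <- array(FALSE, dim)
  m[, , spec$plane] <- d2 <= spec$radius_mm^2
  m
}

#' Measure circular ROIs on a VNCa map
#'
#' Applies the reading protocol: at most 5 lesion ROIs per subject, each with
#' diameter strictly greater than 5 mm (regional ROIs are exempt); returns
#' per-ROI mean and sample SD of the calcium-subtracted HU.
#'
#' @param map a `vnca_map`.
#' @param specs list of [roi_spec()].
#' @return data.frame with kind, label, plane, mean, sd, n_voxels.
#' @export
measure_rois <- function(map, specs) {
  stopifnot(inherits(map, "vnca_map"))
  kinds <- vapply(specs, function(s) s$kind, character(1))
  if (sum(kinds == "lesion") > 5L)
    stop("protocol error: at most 5 lesion ROIs per subject")
  for (s in specs)
    if (s$kind == "lesion" && 2 * s$radius_mm <= 5)
      stop("protocol error: lesion diameter must exceed 5 mm")
  rows <- lapply(specs, function(s) {
    m <- roi_mask(s, dim(map$values), map$spacing)
    x <- map$values[m]
    data.frame(kind = s$kind, label = s$label, plane = s$plane,
               mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
               n_voxels = length(x))
  })
  do.call(rbind, rows)
}
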