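#' Paired-energy CT volume
#'
#' Container for a paired low/high tube-voltage acquisition: two HU voxel
#' grids on the same lattice plus the voxel spacing in mm. Axis order is
#' `(x, y, slice)` with 1-based indices, the R array convention.
#'
#' @param low_energy,high_energy 3-D numeric arrays of HU values, same shape.
#' @param spacing numeric length-3, mm per axis.
#' @return An object of class `dual_energy_volume`.
#' @export
dual_energy_volume <- function(low_energy, high_energy, spacing = c(2, 2, 2)) {
  low_energy <- as.array(low_energy)
  high_energy <- as.array(high_energy)
  if (!identical(dim(low_energy), dim(high_energy)))
    stop("low- and high-energy grids must share a shape")
  if (length(dim(low_energy)) != 3L)
    stop("expected 3-D volumes")
  if (!all(is.finite(low_energy)) || !all(is.finite(high_energy)))
    stop("HU values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive lengths in mm")
  structure(list(low_energy = low_energy, high_energy = high_energy,
                 spacing = spacing),
            class = "dual_energy_volume")
}

#' @export
print.dual_energy_volume <- function(x, ...) {
  cat(sprintf("dual_energy_volume: %s voxels, spacing %s mm\n",
              paste(dim(x$low_energy), collapse = "x"),
              paste(x$spacing, collapse = "x")))
  invisible(x)
}

#' Weighted-average viewing image
#'
#' Linear mix of the two energy images, approximating a conventional
#' single-energy 120 kVp scan. The default 50:50 mix matches routine clinical
#' viewing of 90/150 kVp pairs.
#'
#' @param vol a [dual_energy_volume()].
#' @param mix weight of the low-energy image in `[0, 1]`; default 0.5.
#' @return An object of class `weighted_average_volume` with elements
#'   `values` (HU array), `mix` and `spacing`.
#' @examples
#' v <- dual_energy_volume(array(-108, c(2, 2, 2)), array(-84, c(2, 2, 2)))
#' weighted_average(v)$values[1]  # -96
#' @export
weighted_average <- function(vol, mix = 0.5) {
  stopifnot(inherits(vol, "dual_energy_volume"))
  if (!is.numeric(mix) || length(mix) != 1L || mix < 0 || mix > 1)
    stop("mix must be a single fraction in [0, 1]")
  structure(list(values = mix * vol$low_energy + (1 - mix) * vol$high_energy,
                 mix = mix, spacing = vol$spacing),
            class = "weighted_average_volume")
}

#' Three-material decomposition of a two-energy measurement
#'
#' Solves, exactly and per voxel, the 2x2 linear system
#' `(low, high) = Y + s*(R - Y) + t*(slope, 1)` for the marrow-line coordinate
#' `s` (0 = yellow endpoint, 1 = red endpoint) and the calcium coordinate `t`
#' (HU contributed at the high energy). The virtual non-calcium (VNCa) HU is
#' the attenuation of the calcium-free point `Y + s*(R - Y)`, reported by
#' default as the 50:50 mix of its two-energy coordinates so that VNCa values
#' read on the same scale as the weighted-average viewing images.
#'
#' @param low_hu,high_hu numeric vectors/arrays (recycled together) of HU.
#' @param basis a [material_basis()].
#' @param convention which energy the reported VNCa HU refers to: `"mix"`
#'   (default, 50:50), `"low"` or `"high"`.
#' @return A list with components `vnca`, `s`, `t`, each shaped like the
#'   input.
#' @examples
#' vnca_decompose_voxel(-108, -84)          # yellow endpoint: vnca -96, s 0, t 0
#' vnca_decompose_voxel(57, 16)             # yellow + 100 units of calcium
#' @export
vnca_decompose_voxel <- function(low_hu, high_hu, basis = material_basis(),
                                 convention = c("mix", "low", "high")) {
  stopifnot(inherits(basis, "material_basis"))
  convention <- match.arg(convention)
  if (!identical(dim(low_hu), dim(high_hu)) ||
      length(low_hu) != length(high_hu))
    stop("low and high inputs must share a shape")
  det <- basis_det(basis)
  dl <- low_hu - basis$yellow_low
  dh <- high_hu - basis$yellow_high
  # Cramer's rule on [R-Y | (slope, 1)] [s, t]' = [dl, dh]'
  s <- (dl - basis$calcium_slope * dh) / det
  t <- ((basis$red_low - basis$yellow_low) * dh -
          (basis$red_high - basis$yellow_high) * dl) / det
  marrow_low <- basis$yellow_low + s * (basis$red_low - basis$yellow_low)
  marrow_high <- basis$yellow_high + s * (basis$red_high - basis$yellow_high)
  vnca <- switch(convention,
                 mix = 0.5 * (marrow_low + marrow_high),
                 low = marrow_low,
                 high = marrow_high)
  list(vnca = vnca, s = s, t = t)
}

#' Voxelwise virtual non-calcium map
#'
#' Applies [vnca_decompose_voxel()] to every voxel of a paired-energy volume.
#' The computation is vectorized but contractually identical to a per-voxel
#' loop. No masking is applied here: decomposition runs everywhere (air
#' included) and selecting marrow-bearing voxels is the segmentation stage's
#' job.
#'
#' @param vol a [dual_energy_volume()].
#' @inheritParams vnca_decompose_voxel
#' @param keep_position if `TRUE` (default) the marrow-line coordinate grid
#'   `s` is retained in the result.
#' @return An object of class `vnca_map`: list with `values` (VNCa HU array),
#'   optional `marrow_position`, and `spacing`.
#' @export
vnca_map <- function(vol, basis = material_basis(),
                     convention = c("mix", "low", "high"),
                     keep_position = TRUE) {
  stopifnot(inherits(vol, "dual_energy_volume"))
  convention <- match.arg(convention)
  d <- vnca_decompose_voxel(vol$low_energy, vol$high_energy, basis, convention)
  structure(list(values = d$vnca,
                 marrow_position = if (keep_position) d$s else NULL,
                 spacing = vol$spacing),
            class = "vnca_map")
}

#' @export
print.vnca_map <- function(x, ...) {
  cat(sprintf("vnca_map: %s voxels, HU range [%.1f, %.1f]\n",
              paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}
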