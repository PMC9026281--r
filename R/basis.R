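#' Two-energy material basis for three-material decomposition
#'
#' A `material_basis` fixes the geometry of the calcium / yellow-marrow /
#' red-marrow decomposition: the two-energy Hounsfield coordinates of pure
#' yellow marrow and pure red marrow, and the calcium slope, i.e. the change in
#' low-energy HU per unit change in high-energy HU along the calcium direction.
#' Any voxel `(low, high)` is modelled as
#' `Y + s * (R - Y) + t * (slope, 1)`, where `s` is the position along the
#' marrow line (0 = yellow, 1 = red) and `t` the calcium amount expressed as
#' its high-energy HU contribution.
#'
#' The defaults are the vendor bone-marrow settings for a 90/150 kVp (Sn)
#' acquisition: yellow marrow (-108, -84) HU, red marrow (52, 51) HU, calcium
#' slope 1.65.
#'
#' @param yellow_low,yellow_high HU of pure yellow marrow at the low and high
#'   energy.
#' @param red_low,red_high HU of pure red marrow at the low and high energy.
#' @param calcium_slope dimensionless ratio > 1; calcium attenuates more at
#'   the low energy.
#' @return An object of class `material_basis`.
#' @examples
#' b <- material_basis()
#' b$calcium_slope
#' @export
material_basis <- function(yellow_low = -108, yellow_high = -84,
                           red_low = 52, red_high = 51,
                           calcium_slope = 1.65) {
  b <- list(yellow_low = as.numeric(yellow_low),
            yellow_high = as.numeric(yellow_high),
            red_low = as.numeric(red_low),
            red_high = as.numeric(red_high),
            calcium_slope = as.numeric(calcium_slope))
  if (!all(vapply(b, function(x) length(x) == 1L && is.finite(x), logical(1))))
    stop("all basis entries must be finite scalars")
  if (!(b$yellow_low < b$red_low && b$yellow_high < b$red_high))
    stop("yellow marrow must attenuate less than red marrow at both energies")
  if (b$calcium_slope <= 1)
    stop("calcium_slope must exceed 1 (calcium attenuates more at low energy)")
  if (abs(basis_det(b)) < 1e-8)
    stop("marrow line is parallel to the calcium direction: singular basis")
  class(b) <- "material_basis"
  b
}

# determinant of the 2x2 system [R-Y | (slope, 1)]
basis_det <- function(b) {
  (b$red_low - b$yellow_low) - b$calcium_slope * (b$red_high - b$yellow_high)
}

#' @export
print.material_basis <- function(x, ...) {
  cat("Two-energy material basis (HU at low/high energy)\n")
  cat(sprintf("  yellow marrow: (%g, %g)\n", x$yellow_low, x$yellow_high))
  cat(sprintf("  red marrow:    (%g, %g)\n", x$red_low, x$red_high))
  cat(sprintf("  calcium slope: %g\n", x$calcium_slope))
  invisible(x)
}
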