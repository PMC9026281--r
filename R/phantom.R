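#' Forward two-energy model of a voxel composition
#'
#' Inverse of the three-material decomposition: given marrow fractions and a
#' mineral amount, returns the noiseless paired-energy HU the scanner would
#' measure. Calcium is parameterized by its high-energy HU contribution
#' `calcium_amount`; its low-energy contribution is `calcium_slope` times
#' that, so the stated slope is the single coupling constant.
#'
#' @param yellow_frac,red_frac marrow fractions in `[0, 1]`; must sum to 1
#'   (tolerance 1e-9). Vectorized.
#' @param calcium_amount mineral HU contribution at the high energy, >= 0.
#' @param basis a [material_basis()].
#' @return list with numeric `low` and `high` HU.
#' @examples
#' synthesize_voxel(1, 0, 0)    # pure yellow marrow: (-108, -84)
#' synthesize_voxel(1, 0, 100)  # yellow + calcium: (57, 16)
#' @export
synthesize_voxel <- function(yellow_frac, red_frac, calcium_amount = 0,
                             basis = material_basis()) {
  stopifnot(inherits(basis, "material_basis"))
  if (any(abs(yellow_frac + red_frac - 1) > 1e-9))
    stop("invalid composition: yellow_frac + red_frac must equal 1")
  if (any(calcium_amount < 0))
    stop("calcium_amount must be non-negative")
  list(low = yellow_frac * basis$yellow_low + red_frac * basis$red_low +
         basis$calcium_slope * calcium_amount,
       high = yellow_frac * basis$yellow_high + red_frac * basis$red_high +
         calcium_amount)
}

#' Focal osteolytic lesion specification
#'
#' @param center voxel coordinates `(x, y, slice)`, 1-based.
#' @param diameter_mm lesion diameter in mm, > 0.
#' @param calcium_deficit fraction of local trabecular mineral removed, in
#'   `[0, 1]`.
#' @param red_excess red-marrow fraction added inside the lesion, in `[0, 1]`.
#' @export
lesion_spec <- function(center, diameter_mm, calcium_deficit = 1,
                        red_excess = 0.3) {
  if (diameter_mm <= 0) stop("diameter_mm must be positive")
  if (calcium_deficit < 0 || calcium_deficit > 1 ||
      red_excess < 0 || red_excess > 1)
    stop("lesion fractions must lie in [0, 1]")
  structure(list(center = as.numeric(center), diameter_mm = diameter_mm,
                 calcium_deficit = calcium_deficit, red_excess = red_excess),
            class = "lesion_spec")
}

#' Ground-truth description of one synthetic subject
#'
#' Couples the clinical covariates to the marrow composition the phantom will
#' be built from. The red-marrow fraction is an affine function of biopsy
#' plasma-cell infiltration, `r0 + r1 * infiltration_pct / 100`, clipped to
#' `[0, 1]`; site multipliers scale it per skeletal compartment.
#'
#' @param infiltration_pct plasma-cell infiltration percentage in `[0, 100]`.
#' @param haemoglobin blood haemoglobin, g/L.
#' @param age years.
#' @param red_fraction_params list with `r0`, `r1` (affine link) and
#'   `site_multipliers` (named: spine, long_bone, skull).
#' @param lesions list of [lesion_spec()] objects (at most 5).
#' @param prosthesis logical; if `TRUE` a metal implant replaces part of one
#'   long bone.
#' @param subject_id character label.
#' @export
subject_truth <- function(infiltration_pct, haemoglobin, age,
                          red_fraction_params = list(
                            r0 = 0.2, r1 = 0.6,
                            site_multipliers = c(spine = 1, long_bone = 0.6)),
                          lesions = list(), prosthesis = FALSE,
                          subject_id = "subject") {
  if (infiltration_pct < 0 || infiltration_pct > 100)
    stop("infiltration_pct must lie in [0, 100]")
  if (haemoglobin <= 0) stop("haemoglobin must be positive")
  rf <- red_fraction_params$r0 +
    red_fraction_params$r1 * infiltration_pct / 100
  structure(list(subject_id = subject_id,
                 infiltration_pct = infiltration_pct,
                 haemoglobin = haemoglobin, age = age,
                 red_fraction_params = red_fraction_params,
                 baseline_red_fraction = min(max(rf, 0), 1),
                 lesions = lesions, prosthesis = prosthesis),
            class = "subject_truth")
}

#' Stylized whole-skeleton phantom geometry
#'
#' The phantom is CT-like in topology rather than anatomy: a soft-tissue body
#' cylinder in air containing a spine analog (cortical annulus around a
#' trabecular core around a canal cavity), a skull analog (spherical cortical
#' shell around a brain cavity) and two long-bone tubes with marrow cores.
#' Only the shell-plus-cavity topology matters to the segmentation method.
#'
#' @param dim grid size `(x, y, slices)`; default `c(64, 64, 96)`.
#' @param spacing mm per axis; default 2 mm isotropic.
#' @export
phantom_geometry <- function(dim = c(64, 64, 96), spacing = c(2, 2, 2)) {
  structure(list(
    dim = as.integer(dim), spacing = as.numeric(spacing),
    body = list(center = (dim[1:2] + 1) / 2, radius = 28),
    spine = list(center = (dim[1:2] + 1) / 2, slices = c(9, 72),
                 canal_radius = 3, trabecular_radius = 8,
                 cortical_radius = 10),
    skull = list(center = c((dim[1:2] + 1) / 2, 84),
                 cavity_radius = 8, cortical_radius = 10),
    long_bones = list(centers = list(c(16.5, 32.5), c(48.5, 32.5)),
                      slices = c(6, 40), core_radius = 2,
                      cortical_radius = 4),
    # noiseless tissue HU and mineral amounts (high-energy HU contribution)
    soft_tissue_hu = 35, air_hu = -1000, prosthesis_hu = 10000,
    cortical_calcium = 600, trabecular_calcium = 180),
    class = "phantom_geometry")
}

#' Draw a synthetic patient cohort
#'
#' Samples per-subject covariates with the dependence structure the analysis
#' assumes: infiltration percentage from three equal strata (<=10%, 11-60%,
#' >60%), a monotone coupling of the marrow red fraction to infiltration
#' whose strength is `rho_inf` (1 = deterministic affine link, 0 =
#' independent), and haemoglobin decreasing in infiltration with slope
#' `hb_slope` plus Gaussian noise. Lesion count (0-5) rises with
#' infiltration; about 15% of subjects carry a prosthesis.
#'
#' @param n number of subjects, >= 2.
#' @param coupling list with `rho_inf` in `[0, 1]` and `hb_slope` (g/L per
#'   infiltration percent, usually negative).
#' @param seed integer seed; all randomness is derived from it.
#' @param geometry a [phantom_geometry()], used to place lesions inside the
#'   spine's trabecular compartment.
#' @return list of [subject_truth()] objects.
#' @export
sample_cohort <- function(n, coupling = list(rho_inf = 0.9, hb_slope = -0.35),
                          seed = 1, geometry = phantom_geometry()) {
  if (n < 2) stop("cohort too small: need n >= 2")
  rho <- coupling$rho_inf
  if (is.null(rho) || rho < 0 || rho > 1)
    stop("coupling$rho_inf must lie in [0, 1]")
  hb_slope <- if (is.null(coupling$hb_slope)) -0.35 else coupling$hb_slope
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    stratum <- sample.int(3L, 1L)
    inf <- switch(stratum, stats::runif(1, 0, 10), stats::runif(1, 11, 60),
                  stats::runif(1, 60, 95))
    # mixing an independent uniform dials the monotone strength down from 1
    z <- rho * inf + (1 - rho) * stats::runif(1, 0, 100)
    hb <- max(145 + hb_slope * inf + stats::rnorm(1, 0, 8), 60)
    age <- min(max(round(stats::rnorm(1, 67, 8)), 35), 90)
    n_les <- stats::rbinom(1, 5, min(0.25 + 0.0025 * inf, 0.95))
    lesions <- replicate(n_les, sample_spine_lesion(geometry),
                         simplify = FALSE)
    truth <- subject_truth(
      infiltration_pct = inf, haemoglobin = hb, age = age,
      lesions = lesions,
      prosthesis = stats::runif(1) < 0.15,
      subject_id = sprintf("S%03d", i))
    # override the baseline with the noise-mixed link
    truth$baseline_red_fraction <- min(max(0.2 + 0.6 * z / 100, 0), 1)
    truth
  })
}

# one lesion entirely inside the spine trabecular annulus
sample_spine_lesion <- function(geometry) {
  sp <- geometry$spine
  diameter <- stats::runif(1, 6, 9)
  r_vox <- diameter / 2 / geometry$spacing[1]
  # radial band keeping the sphere clear of canal and cortex
  lo <- sp$canal_radius + r_vox + 0.1
  hi <- sp$trabecular_radius - r_vox - 0.1
  d <- stats::runif(1, lo, hi)
  ang <- stats::runif(1, 0, 2 * pi)
  z <- sample(seq(sp$slices[1] + ceiling(r_vox) + 1,
                  sp$slices[2] - ceiling(r_vox) - 1), 1)
  lesion_spec(center = c(sp$center[1] + d * cos(ang),
                         sp$center[2] + d * sin(ang), z),
              diameter_mm = diameter,
              calcium_deficit = stats::runif(1, 0.6, 1),
              red_excess = stats::runif(1, 0.2, 0.5))
}

#' Build one synthetic dual-energy volume with its ground truth
#'
#' Rasterizes the stylized skeleton, forms the two-energy HU via the forward
#' material model ([synthesize_voxel()]), applies lesions and the optional
#' prosthesis, and adds independent zero-mean Gaussian noise per energy.
#' Cortical voxels carry enough mineral that their noiseless low-energy HU
#' exceeds the 120 HU segmentation threshold everywhere.
#'
#' @param truth a [subject_truth()].
#' @param geometry a [phantom_geometry()].
#' @param noise_sd HU noise standard deviation per energy image; default 15.
#' @param seed integer seed for the noise draw.
#' @param basis a [material_basis()].
#' @return list with `volume` (a [dual_energy_volume()]) and `truth_masks`,
#'   a list of logical arrays `skeleton_mask`, `cavity_mask`, `lesion_mask`,
#'   `prosthesis_mask` plus the numeric `voxel_red_fraction` grid.
#' @export
build_phantom <- function(truth, geometry = phantom_geometry(),
                          noise_sd = 15, seed = 1,
                          basis = material_basis()) {
  stopifnot(inherits(truth, "subject_truth"),
            inherits(geometry, "phantom_geometry"))
  dm <- geometry$dim
  lab <- rasterize_geometry(geometry)   # integer label array
  mult <- truth$red_fraction_params$site_multipliers
  rf0 <- truth$baseline_red_fraction

  red <- array(0, dm)
  calcium <- array(0, dm)
  red[lab == LAB$spine_trab] <- min(max(rf0 * mult[["spine"]], 0), 1)
  red[lab == LAB$bone_core] <- min(max(rf0 * mult[["long_bone"]], 0), 1)
  trabecular <- lab == LAB$spine_trab | lab == LAB$bone_core
  calcium[trabecular] <- geometry$trabecular_calcium
  cortical <- lab == LAB$cortical
  calcium[cortical] <- geometry$cortical_calcium

  lesion_mask <- array(FALSE, dm)
  for (les in truth$lesions) {
    vox <- sphere_voxels(les$center, les$diameter_mm / 2, geometry)
    if (!all(trabecular[vox]))
      stop("lesion placement error: sphere leaves the trabecular compartment")
    lesion_mask[vox] <- TRUE
    calcium[vox] <- calcium[vox] * (1 - les$calcium_deficit)
    red[vox] <- pmin(red[vox] + les$red_excess, 1)
  }

  marrow <- trabecular | cortical
  hu <- synthesize_voxel(1 - red[marrow], red[marrow], calcium[marrow], basis)
  low <- array(geometry$air_hu, dm)
  high <- array(geometry$air_hu, dm)
  soft <- lab == LAB$soft | lab == LAB$cavity
  low[soft] <- geometry$soft_tissue_hu
  high[soft] <- geometry$soft_tissue_hu
  low[marrow] <- hu$low
  high[marrow] <- hu$high

  prosthesis_mask <- array(FALSE, dm)
  if (isTRUE(truth$prosthesis)) {
    prosthesis_mask <- rasterize_prosthesis(geometry)
    low[prosthesis_mask] <- geometry$prosthesis_hu
    high[prosthesis_mask] <- geometry$prosthesis_hu
  }

  if (noise_sd > 0) {
    set.seed(seed)
    low <- low + stats::rnorm(length(low), 0, noise_sd)
    high <- high + stats::rnorm(length(high), 0, noise_sd)
  }

  skeleton_mask <- marrow & !prosthesis_mask
  cavity_mask <- lab == LAB$cavity
  red[!skeleton_mask] <- 0
  list(volume = dual_energy_volume(low, high, geometry$spacing),
       truth_masks = list(skeleton_mask = skeleton_mask,
                          cavity_mask = cavity_mask,
                          lesion_mask = lesion_mask & skeleton_mask,
                          prosthesis_mask = prosthesis_mask,
                          voxel_red_fraction = red))
}

LAB <- list(air = 0L, soft = 1L, cavity = 2L, cortical = 3L,
            spine_trab = 4L, bone_core = 5L)

# label every voxel of the stylized skeleton; later labels overwrite earlier
rasterize_geometry <- function(geometry) {
  dm <- geometry$dim
  x <- seq_len(dm[1]); y <- seq_len(dm[2]); z <- seq_len(dm[3])
  lab <- array(LAB$air, dm)

  r2_body <- outer((x - geometry$body$center[1])^2,
                   (y - geometry$body$center[2])^2, "+")
  body <- array(r2_body <= geometry$body$radius^2, dm)
  lab[body] <- LAB$soft

  sp <- geometry$spine
  r2 <- outer((x - sp$center[1])^2, (y - sp$center[2])^2, "+")
  in_z <- z >= sp$slices[1] & z <= sp$slices[2]
  zs <- array(rep(in_z, each = dm[1] * dm[2]), dm)
  r2a <- array(r2, dm)
  lab[zs & r2a <= sp$cortical_radius^2] <- LAB$cortical
  lab[zs & r2a <= sp$trabecular_radius^2] <- LAB$spine_trab
  lab[zs & r2a <= sp$canal_radius^2] <- LAB$cavity

  lb <- geometry$long_bones
  in_zb <- z >= lb$slices[1] & z <= lb$slices[2]
  zsb <- array(rep(in_zb, each = dm[1] * dm[2]), dm)
  for (ctr in lb$centers) {
    r2b <- array(outer((x - ctr[1])^2, (y - ctr[2])^2, "+"), dm)
    lab[zsb & r2b <= lb$cortical_radius^2] <- LAB$cortical
    lab[zsb & r2b <= lb$core_radius^2] <- LAB$bone_core
  }

  sk <- geometry$skull
  r2s <- outer(outer((x - sk$center[1])^2, (y - sk$center[2])^2, "+"),
               (z - sk$center[3])^2, "+")
  lab[r2s <= sk$cortical_radius^2] <- LAB$cortical
  lab[r2s <= sk$cavity_radius^2] <- LAB$cavity
  lab
}

# metal segment replacing the lower half of the first long bone
rasterize_prosthesis <- function(geometry) {
  dm <- geometry$dim
  x <- seq_len(dm[1]); y <- seq_len(dm[2]); z <- seq_len(dm[3])
  lb <- geometry$long_bones
  ctr <- lb$centers[[1]]
  r2 <- array(outer((x - ctr[1])^2, (y - ctr[2])^2, "+"), dm)
  in_z <- z >= lb$slices[1] + 2 & z <= lb$slices[1] + 14
  zs <- array(rep(in_z, each = dm[1] * dm[2]), dm)
  zs & r2 <= lb$cortical_radius^2
}

# linear indices of voxels whose centres lie within radius_mm of a point
sphere_voxels <- function(center, radius_mm, geometry) {
  dm <- geometry$dim
  sp <- geometry$spacing
  rv <- radius_mm / sp
  rng <- function(c, r, n) max(1L, floor(c - r)):min(n, ceiling(c + r))
  g <- expand.grid(x = rng(center[1], rv[1], dm[1]),
                   y = rng(center[2], rv[2], dm[2]),
                   z = rng(center[3], rv[3], dm[3]))
  d2 <- ((g$x - center[1]) * sp[1])^2 + ((g$y - center[2]) * sp[2])^2 +
    ((g$z - center[3]) * sp[3])^2
  g <- g[d2 <= radius_mm^2, , drop = FALSE]
  if (nrow(g) == 0) stop("lesion placement error: empty sphere")
  (g$z - 1L) * dm[1] * dm[2] + (g$y - 1L) * dm[1] + g$x
}

#' Clinical covariate table of a sampled cohort
#'
#' @param cohort list of [subject_truth()] from [sample_cohort()].
#' @return data.frame with subject_id, infiltration_pct, haemoglobin, age.
#' @export
cohort_covariates <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort, function(s) s$subject_id, character(1)),
    infiltration_pct = vapply(cohort, function(s) s$infiltration_pct,
                              numeric(1)),
    haemoglobin = vapply(cohort, function(s) s$haemoglobin, numeric(1)),
    age = vapply(cohort, function(s) s$age, numeric(1)))
}
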