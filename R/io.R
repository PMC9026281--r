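#' Read a scalar NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with numeric `values` array and `spacing` (mm per axis).
#' @export
read_volume <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("expected a NIfTI path (.nii or .nii.gz): ", path)
  if (!file.exists(path)) stop("volume not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    if (prod(d[-(1:3)]) != 1L) stop("non-scalar NIfTI data in ", path)
    dim(img) <- d[1:3]
  }
  list(values = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img)[seq_along(dim(img))])
}

#' Write a scalar NIfTI volume
#'
#' @param values numeric or logical array.
#' @param spacing mm per axis.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, spacing, path) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("expected a NIfTI path (.nii or .nii.gz): ", path)
  img <- RNifti::asNifti(array(as.numeric(values), dim(values)))
  img <- RNifti::`pixdim<-`(img, as.numeric(spacing))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read/write a paired-energy volume as two NIfTI files
#'
#' The pair is stored as `<prefix>_90kv.nii.gz` and `<prefix>_150kv.nii.gz`.
#'
#' @param vol a [dual_energy_volume()].
#' @param prefix path prefix.
#' @return For the writer, the two paths invisibly; for the reader, a
#'   [dual_energy_volume()].
#' @export
write_dual_energy <- function(vol, prefix) {
  stopifnot(inherits(vol, "dual_energy_volume"))
  p1 <- paste0(prefix, "_90kv.nii.gz")
  p2 <- paste0(prefix, "_150kv.nii.gz")
  write_volume(vol$low_energy, vol$spacing, p1)
  write_volume(vol$high_energy, vol$spacing, p2)
  invisible(c(p1, p2))
}

#' @rdname write_dual_energy
#' @export
read_dual_energy <- function(prefix) {
  lo <- read_volume(paste0(prefix, "_90kv.nii.gz"))
  hi <- read_volume(paste0(prefix, "_150kv.nii.gz"))
  dual_energy_volume(lo$values, hi$values, lo$spacing)
}

#' Published reference cohort of whole-skeleton histogram values
#'
#' Per-patient whole-skeleton calcium-subtracted histogram summaries (mean,
#' median, SD, skewness, kurtosis in HU where applicable) for a published
#' 21-patient myeloma dual-energy CT cohort, shipped with the package so the
#' cohort summary statistics can be recomputed from printed data.
#'
#' @return data.frame with columns `patient_id`, `diagnosis`, `mean`,
#'   `median`, `sd`, `skewness`, `kurtosis`.
#' @examples
#' cohort_median_iqr(reference_cohort()$mean)
#' @export
reference_cohort <- function() {
  path <- system.file("extdata", "reference_cohort_histograms.csv",
                      package = "vncaskel", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
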