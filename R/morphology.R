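# Internal 3-D binary morphology on logical arrays.
#
# Erosion/dilation are computed as AND/OR over integer-shifted copies of the
# array; borders are handled by edge replication. The curvature-smoothing
# operators used by the morphological active contour are built from the
# standard set of nine 3x3x3 planar structuring elements (the three
# axis-aligned planes through the centre plus the six diagonal planes), each
# expressed as a 9-row offset matrix.

shift3 <- function(a, d) {
  dm <- dim(a)
  ix <- pmin(pmax(seq_len(dm[1]) + d[1], 1L), dm[1])
  iy <- pmin(pmax(seq_len(dm[2]) + d[2], 1L), dm[2])
  iz <- pmin(pmax(seq_len(dm[3]) + d[3], 1L), dm[3])
  a[ix, iy, iz, drop = FALSE]
}

# offsets: n x 3 integer matrix
erode_se <- function(u, offsets) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift3(u, offsets[i, ])
    out <- if (is.null(out)) s else out & s
  }
  out
}

dilate_se <- function(u, offsets) {
  out <- NULL
  for (i in seq_len(nrow(offsets))) {
    s <- shift3(u, offsets[i, ])
    out <- if (is.null(out)) s else out | s
  }
  out
}

se_full26 <- local({
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  storage.mode(g) <- "integer"
  g
})

erode26 <- function(u) erode_se(u, se_full26)
dilate26 <- function(u) dilate_se(u, se_full26)

# the nine planar elements, each 9 offsets: (i, j) range over -1:1
plane_ses <- local({
  mk <- function(f) {
    off <- matrix(0L, 9L, 3L)
    k <- 1L
    for (i in -1:1) for (j in -1:1) {
      off[k, ] <- f(i, j)
      k <- k + 1L
    }
    off
  }
  list(
    mk(function(i, j) c(i, j, 0L)),   # xy plane
    mk(function(i, j) c(i, 0L, j)),   # xz plane
    mk(function(i, j) c(0L, i, j)),   # yz plane
    mk(function(i, j) c(i, j, j)),    # diagonal planes
    mk(function(i, j) c(i, j, -j)),
    mk(function(i, j) c(j, i, j)),
    mk(function(i, j) c(j, i, -j)),
    mk(function(i, j) c(j, j, i)),
    mk(function(i, j) c(j, -j, i))
  )
})

# sup of infima / inf of suprema over the planar element set
sup_inf <- function(u) {
  out <- NULL
  for (se in plane_ses) {
    e <- erode_se(u, se)
    out <- if (is.null(out)) e else out | e
  }
  out
}

inf_sup <- function(u) {
  out <- NULL
  for (se in plane_ses) {
    d <- dilate_se(u, se)
    out <- if (is.null(out)) d else out & d
  }
  out
}

# one curvature-smoothing round; parity alternates the operator order
curvature_smooth <- function(u, parity) {
  if (parity %% 2L == 0L) sup_inf(inf_sup(u)) else inf_sup(sup_inf(u))
}

# fill 2-D holes of one axial cross-section (EBImage works frame-wise in 2-D)
fill_slice_holes <- function(mask, slice) {
  m <- mask[, , slice, drop = TRUE]
  filled <- EBImage::fillHull(matrix(as.integer(m), nrow(m), ncol(m)))
  mask[, , slice] <- as.logical(filled)
  mask
}
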