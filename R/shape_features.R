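# The ten shape features. Volume and principal-axis quantities are
# computed directly on the voxel grid; surface area and Feret diameters
# on a watertight triangulated isosurface. Everything works in physical
# mm, so anisotropic spacing needs no resampling.

.assertNonEmpty <- function(mask) {
  if (!any(mask@occupancy)) stop("empty ROI: mask has no occupied voxels")
}

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "VoxelMask", function(mask) {
  .assertNonEmpty(mask)
  sum(mask@occupancy) * prod(mask@spacing)
})

# Physical coordinates (mm) of occupied voxel centers, n x 3.
.occupiedCoords <- function(mask) {
  idx <- which(mask@occupancy, arr.ind = TRUE) - 1L
  sweep(idx %*% diag(mask@spacing), 2, mask@origin, "+")
}

#' @rdname buildSurfaceMesh
#' @export
setMethod("buildSurfaceMesh", "VoxelMask",
          function(mask, smoothingSigma = 1) {
  .assertNonEmpty(mask)
  stopifnot(is.numeric(smoothingSigma), smoothingSigma >= 0)
  level <- 0.5
  occ <- mask@occupancy
  # pad so boundary-touching ROIs still produce a closed surface; the
  # pad also absorbs the smoothing kernel support
  sigma <- smoothingSigma
  repeat {
    padN <- max(2L, as.integer(ceiling(3 * sigma)) + 1L)
    d <- dim(occ) + 2L * padN
    field <- array(0, d)
    field[(padN + 1):(padN + dim(occ)[1]),
          (padN + 1):(padN + dim(occ)[2]),
          (padN + 1):(padN + dim(occ)[3])] <- as.numeric(occ)
    if (sigma > 0)
      field <- .cppGaussianSmooth3D(field, dim(field), rep(sigma, 3))
    if (max(field) > level + 1e-6) break
    # ROI too small to keep an interior above the iso-level at this
    # bandwidth: halve sigma, down to the raw binary grid
    sigma <- if (sigma > 0.25) sigma / 2 else 0
    if (sigma == 0 && max(field) <= level + 1e-6) {
      field <- array(0, d)
      field[(padN + 1):(padN + dim(occ)[1]),
            (padN + 1):(padN + dim(occ)[2]),
            (padN + 1):(padN + dim(occ)[3])] <- as.numeric(occ)
      break
    }
  }
  # snap values numerically equal to the level just below it so that
  # interpolated vertices stay strictly inside grid edges
  field[abs(field - level) < 1e-9] <- level - 1e-9
  orig <- mask@origin - padN * mask@spacing
  res <- .cppMarchingTetrahedra(field, dim(field), mask@spacing, orig, level)
  new("SurfaceMesh", vertices = res$vertices,
      triangles = res$triangles)
})

#' @rdname surfaceArea
#' @export
setMethod("surfaceArea", "SurfaceMesh", function(mesh) {
  v <- mesh@vertices; f <- mesh@triangles
  if (nrow(f) == 0L) return(0)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(0.5 * sqrt(cx^2 + cy^2 + cz^2))
})

#' @rdname maxDiameter3D
#' @export
setMethod("maxDiameter3D", "SurfaceMesh", function(mesh) {
  if (nrow(mesh@vertices) < 2L)
    stop("need at least 2 vertices for a Feret diameter")
  .cppMaxPairwiseDist(mesh@vertices, 1:3)
})

.PLANES <- list(slice = c(2L, 3L),   # row-column plane: drop slice axis
                column = c(1L, 2L),  # row-slice plane: drop column axis
                row = c(1L, 3L))     # column-slice plane: drop row axis

#' @rdname maxDiameter2D
#' @export
setMethod("maxDiameter2D", "SurfaceMesh", function(mesh, plane) {
  if (nrow(mesh@vertices) < 2L)
    stop("need at least 2 vertices for a Feret diameter")
  if (!is.character(plane) || length(plane) != 1L ||
      !plane %in% names(.PLANES))
    stop("plane must be one of: ", paste(names(.PLANES), collapse = ", "))
  .cppMaxPairwiseDist(mesh@vertices, .PLANES[[plane]])
})

#' @rdname axisLengths
#' @export
setMethod("axisLengths", "VoxelMask", function(mask) {
  .assertNonEmpty(mask)
  xyz <- .occupiedCoords(mask)
  n <- nrow(xyz)
  if (n == 1L) {
    warning("single-voxel mask: all principal axis lengths are 0")
    return(list(major = 0, minor = 0, least = 0, eigenvalues = c(0, 0, 0)))
  }
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  cov <- crossprod(xc) / n  # population covariance
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (any(ev < -1e-12)) stop("negative covariance eigenvalue: ", min(ev))
  ev <- pmax(ev, 0)
  list(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(ev[2]),
       least = 4 * sqrt(ev[3]), eigenvalues = ev)
})

#' Flatness from principal-component eigenvalues
#'
#' `sqrt(lambda_least / lambda_major)`: 1 for a sphere-like object, 0
#' for a flat object or single-slice segmentation. Eigenvalues within
#' 1e-12 of zero are clamped to zero first; genuinely negative values
#' are an error.
#'
#' @param eigenvalues numeric(3) sorted descending (as returned by
#'   [axisLengths()]), or any numeric vector whose max/min are used.
#' @return flatness in [0, 1]; NA with a warning when the major
#'   eigenvalue is 0 (degenerate point mask).
#' @export
flatnessFromEigenvalues <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  if (any(ev < -1e-12))
    stop("negative eigenvalue passed to flatness: ", min(ev))
  ev <- pmax(ev, 0)
  lmaj <- max(ev); llst <- min(ev)
  if (lmaj == 0) {
    warning("flatness undefined for zero major eigenvalue")
    return(NA_real_)
  }
  sqrt(llst / lmaj)
}

#' @rdname extractFeatures
#' @export
setMethod("extractFeatures", "VoxelMask",
          function(mask, smoothingSigma = 1) {
  .assertNonEmpty(mask)
  mesh <- buildSurfaceMesh(mask, smoothingSigma = smoothingSigma)
  ax <- withCallingHandlers(
    axisLengths(mask),
    warning = function(w) invokeRestart("muffleWarning"))
  fl <- if (max(ax$eigenvalues) == 0) 0 else
    flatnessFromEigenvalues(ax$eigenvalues)
  vals <- c(voxel_volume = voxelVolume(mask),
            surface_area = surfaceArea(mesh),
            max_3d_diameter = maxDiameter3D(mesh),
            max_2d_diameter_slice = maxDiameter2D(mesh, "slice"),
            max_2d_diameter_column = maxDiameter2D(mesh, "column"),
            max_2d_diameter_row = maxDiameter2D(mesh, "row"),
            minor_axis_length = ax$minor,
            major_axis_length = ax$major,
            least_axis_length = ax$least,
            flatness = fl)
  new("ShapeFeatures", values = vals)
})
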