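#' @rdname VoxelMask-class
#' @param object,x a `VoxelMask`
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname VoxelMask-class
#' @export
setGeneric("maskSpacing", function(x) standardGeneric("maskSpacing"))

#' @rdname VoxelMask-class
#' @export
setGeneric("maskOrigin", function(x) standardGeneric("maskOrigin"))

#' @rdname VoxelMask-class
#' @export
setGeneric("nOccupied", function(x) standardGeneric("nOccupied"))

#' @rdname VoxelMask-class
#' @export
setGeneric("isEmptyMask", function(x) standardGeneric("isEmptyMask"))

#' @rdname SurfaceMesh-class
#' @param x a `SurfaceMesh`
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname SurfaceMesh-class
#' @export
setGeneric("meshTriangles", function(x) standardGeneric("meshTriangles"))

#' Total voxel volume of a mask
#'
#' Number of occupied voxels times the volume of a single voxel
#' (the product of the three spacing components).
#'
#' @param mask a [VoxelMask] with at least one occupied voxel.
#' @return volume in mm^3.
#' @export
setGeneric("voxelVolume", function(mask) standardGeneric("voxelVolume"))

#' Triangulated isosurface of a mask
#'
#' @param mask a non-empty [VoxelMask].
#' @param smoothingSigma Gaussian pre-smoothing bandwidth in voxels
#'   applied to the padded binary grid before isosurface extraction
#'   (default 1). Automatically reduced for ROIs too small to retain an
#'   interior above the iso-level; 0 meshes the raw binary grid.
#' @return a closed [SurfaceMesh] in physical mm.
#' @export
setGeneric("buildSurfaceMesh",
  function(mask, smoothingSigma = 1) standardGeneric("buildSurfaceMesh"))

#' Mesh surface area
#'
#' Sum over triangles of half the magnitude of the cross product of two
#' edge vectors.
#'
#' @param mesh a [SurfaceMesh].
#' @return area in mm^2.
#' @export
setGeneric("surfaceArea", function(mesh) standardGeneric("surfaceArea"))

#' Maximum 3D (Feret) diameter
#'
#' Largest pairwise Euclidean distance between surface-mesh vertices.
#'
#' @param mesh a [SurfaceMesh] with at least two vertices.
#' @return length in mm.
#' @export
setGeneric("maxDiameter3D", function(mesh) standardGeneric("maxDiameter3D"))

#' Maximum in-plane 2D diameter
#'
#' Largest pairwise Euclidean distance between surface-mesh vertices
#' after dropping the coordinate orthogonal to the named plane:
#' `"slice"` drops the slice axis (row-column, generally axial),
#' `"column"` drops the column axis (row-slice, usually coronal),
#' `"row"` drops the row axis (column-slice, usually sagittal).
#'
#' @param mesh a [SurfaceMesh] with at least two vertices.
#' @param plane one of "slice", "column", "row".
#' @return length in mm.
#' @export
setGeneric("maxDiameter2D",
  function(mesh, plane) standardGeneric("maxDiameter2D"))

#' Principal-component axis lengths of a mask
#'
#' Eigenvalues of the population covariance (divide by N) of occupied
#' voxel-center physical coordinates, sorted descending; each axis
#' length is 4 * sqrt(lambda), the axis length of the ROI-enclosing
#' ellipsoid. A mask confined to a single grid plane has least axis
#' length 0; a single voxel gives all zeros (with a warning).
#'
#' @param mask a non-empty [VoxelMask].
#' @return list with `major`, `minor`, `least` (mm) and `eigenvalues`
#'   (numeric(3), descending, mm^2).
#' @export
setGeneric("axisLengths", function(mask) standardGeneric("axisLengths"))

#' All ten shape features of a mask
#'
#' @param mask a non-empty [VoxelMask].
#' @param smoothingSigma passed to [buildSurfaceMesh()].
#' @return a [ShapeFeatures].
#' @export
setGeneric("extractFeatures",
  function(mask, smoothingSigma = 1) standardGeneric("extractFeatures"))

#' @rdname ShapeFeatures-class
#' @param x a `ShapeFeatures`
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname CohortManifest-class
#' @param x a `CohortManifest`
#' @export
setGeneric("manifestData", function(x) standardGeneric("manifestData"))

#' @rdname CohortManifest-class
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
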