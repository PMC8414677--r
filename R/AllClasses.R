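#' @useDynLib MCmorph, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' VoxelMask: a binary 3D segmentation on a regular grid
#'
#' A `VoxelMask` holds the occupancy grid of a segmented region of
#' interest together with its physical geometry. Grid axes are ordered
#' (slice, row, column); the physical position of the voxel at 0-based
#' index (i, j, k) is `origin + c(i, j, k) * spacing`, i.e. coordinates
#' are voxel-center based.
#'
#' @slot occupancy 3D `logical` array, axes (slice, row, column).
#' @slot spacing numeric(3), strictly positive voxel edge lengths in mm
#'   per axis, same order as the grid axes.
#' @slot origin numeric(3), physical offset in mm of the center of voxel
#'   (0, 0, 0).
#'
#' @seealso [readMask()], [writeMask()], [makePhantom()]
#' @export
setClass("VoxelMask",
  representation(occupancy = "array", spacing = "numeric", origin = "numeric"),
  prototype(occupancy = array(FALSE, c(1, 1, 1)),
            spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("VoxelMask", function(object) {
  msg <- character()
  if (length(dim(object@occupancy)) != 3L)
    msg <- c(msg, "occupancy must be a 3D array")
  if (!is.logical(object@occupancy))
    msg <- c(msg, "occupancy must be logical (binary)")
  if (anyNA(object@occupancy))
    msg <- c(msg, "occupancy must not contain NA")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three strictly positive lengths (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be three finite offsets (mm)")
  if (length(msg)) msg else TRUE
})

#' SurfaceMesh: a triangulated isosurface
#'
#' Vertices are physical coordinates in mm, in the same (slice, row,
#' column) axis order as [VoxelMask]. Triangles index rows of the vertex
#' matrix (1-based). Meshes produced by [buildSurfaceMesh()] are closed:
#' every undirected edge is shared by exactly two triangles.
#'
#' @slot vertices numeric matrix, n x 3, mm.
#' @slot triangles integer matrix, m x 3, 1-based vertex indices.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix"))

setValidity("SurfaceMesh", function(object) {
  msg <- character()
  v <- object@vertices; f <- object@triangles
  if (!is.numeric(v) || ncol(v) != 3L)
    msg <- c(msg, "vertices must be a numeric n x 3 matrix")
  if (!is.numeric(f) || ncol(f) != 3L)
    msg <- c(msg, "triangles must be an integer m x 3 matrix")
  else if (nrow(f) > 0 && (min(f) < 1L || max(f) > nrow(v)))
    msg <- c(msg, "triangle indices out of range")
  if (length(msg)) msg else TRUE
})

#' ShapeFeatures: the ten per-mask shape descriptors
#'
#' A fixed-length named numeric vector wrapped in S4: voxel volume
#' (mm^3), surface area (mm^2), maximum 3D diameter and the three
#' in-plane maximum 2D diameters (mm), major/minor/least principal-axis
#' lengths (mm), and flatness (dimensionless, 1 = sphere-like, 0 = flat
#' or single-slice).
#'
#' @slot values named numeric(10); names as in [featureNames()].
#' @seealso [extractFeatures()]
#' @export
setClass("ShapeFeatures", representation(values = "numeric"))

#' Canonical feature names
#'
#' Internal column names of the ten shape features, in canonical order,
#' and their display names as used in reported tables.
#'
#' @return character(10).
#' @export
featureNames <- function() {
  c("voxel_volume", "surface_area", "max_3d_diameter",
    "max_2d_diameter_slice", "max_2d_diameter_column",
    "max_2d_diameter_row", "minor_axis_length", "major_axis_length",
    "least_axis_length", "flatness")
}

#' @rdname featureNames
#' @export
featureDisplayNames <- function() {
  c(voxel_volume = "Voxel Volume (mm3)",
    surface_area = "Surface Area (mm2)",
    max_3d_diameter = "Maximum 3D Diameter (mm)",
    max_2d_diameter_slice = "Maximum 2D Diameter Slice (mm)",
    max_2d_diameter_column = "Maximum 2D Diameter Column (mm)",
    max_2d_diameter_row = "Maximum 2D Diameter Row (mm)",
    minor_axis_length = "Minor Axis Length (mm)",
    major_axis_length = "Major Axis Length (mm)",
    least_axis_length = "Least Axis Length (mm)",
    flatness = "Flatness")
}

setValidity("ShapeFeatures", function(object) {
  v <- object@values
  msg <- character()
  if (!identical(names(v), featureNames()))
    msg <- c(msg, "values must be named exactly featureNames(), in order")
  lengths <- v[setdiff(featureNames(), "flatness")]
  if (any(!is.na(lengths) & lengths < 0))
    msg <- c(msg, "lengths, areas and volumes must be nonnegative")
  fl <- v[["flatness"]]
  if (!is.na(fl) && (fl < 0 || fl > 1))
    msg <- c(msg, "flatness must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' CohortManifest: per-subject bilateral study bookkeeping
#'
#' Wraps a validated data.frame with one row per subject: group
#' ("PTN"/"HC"), affected side ("left"/"right"/"none"), per-side
#' neurovascular-contact flags ("yes"/"no"), and paths (or in-memory
#' keys) for the left and right masks. Optional `age` and `sex`
#' ("male"/"female") columns feed the demographics table.
#'
#' Invariants enforced: unique subject ids; HC rows have affected side
#' "none"; PTN rows have affected side "left" or "right".
#'
#' @slot data data.frame with columns subject_id, group, affected_side,
#'   nvc_left, nvc_right, mask_left, mask_right (+ optional age, sex).
#' @seealso [readManifest()]
#' @export
setClass("CohortManifest", representation(data = "data.frame"))

.manifestRequired <- c("subject_id", "group", "affected_side",
                       "nvc_left", "nvc_right", "mask_left", "mask_right")

setValidity("CohortManifest", function(object) {
  d <- object@data
  msg <- character()
  miss <- setdiff(.manifestRequired, names(d))
  if (length(miss))
    return(paste("missing manifest columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(d$subject_id)) {
    dup <- unique(d$subject_id[duplicated(d$subject_id)])
    msg <- c(msg, paste("duplicated subject ids:", paste(dup, collapse = ", ")))
  }
  bad <- !d$group %in% c("PTN", "HC")
  if (any(bad))
    msg <- c(msg, paste("unknown group token in rows:",
                        paste(which(bad), collapse = ", ")))
  bad <- !d$affected_side %in% c("left", "right", "none")
  if (any(bad))
    msg <- c(msg, paste("unknown affected_side token in rows:",
                        paste(which(bad), collapse = ", ")))
  hcbad <- d$group == "HC" & d$affected_side != "none"
  if (any(hcbad))
    msg <- c(msg, paste("HC rows must have affected_side 'none':",
                        paste(which(hcbad), collapse = ", ")))
  ptnbad <- d$group == "PTN" & !d$affected_side %in% c("left", "right")
  if (any(ptnbad))
    msg <- c(msg, paste("PTN rows must have affected_side left/right:",
                        paste(which(ptnbad), collapse = ", ")))
  for (cc in c("nvc_left", "nvc_right")) {
    bad <- !d[[cc]] %in% c("yes", "no")
    if (any(bad))
      msg <- c(msg, paste0("column ", cc, " must be yes/no; bad rows: ",
                           paste(which(bad), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' ComparisonResult: one statistical contrast
#'
#' @slot contrast character label of the comparison.
#' @slot test name of the statistical test.
#' @slot n numeric(2), per-arm sample sizes.
#' @slot mean numeric(2), per-arm means.
#' @slot sd numeric(2), per-arm standard deviations.
#' @slot statistic test statistic (NA when flagged).
#' @slot p p-value in [0, 1] (NA when flagged).
#' @slot paired logical flag.
#' @slot note character; non-empty when the contrast was flagged
#'   (e.g. stratum too small, zero variance) instead of tested.
#' @export
setClass("ComparisonResult",
  representation(contrast = "character", test = "character",
                 n = "numeric", mean = "numeric", sd = "numeric",
                 statistic = "numeric", p = "numeric",
                 paired = "logical", note = "character"))

setValidity("ComparisonResult", function(object) {
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    "p-value must lie in [0, 1]" else TRUE
})
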