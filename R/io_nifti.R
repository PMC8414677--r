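# NIfTI-1 mask I/O and cohort manifests. All coordinate and spacing
# conventions live here: the package grid order is (slice, row, column),
# mapped once at read time from NIfTI storage order (i, j, k) =
# (column, row, slice). Physical position of 0-based grid index v is
# origin + v * spacing (voxel centers).

.AXPERM <- c(3L, 2L, 1L)  # NIfTI (i,j,k) <-> mask (slice,row,column)

#' Construct a VoxelMask
#'
#' @param occupancy 3D array; any nonzero (or TRUE) value counts as
#'   occupied, so label maps from arbitrary exporters are accepted.
#' @param spacing numeric(3) voxel edge lengths in mm, (slice, row,
#'   column) order.
#' @param origin numeric(3) physical position in mm of voxel (0,0,0).
#' @return a [VoxelMask].
#' @export
VoxelMask <- function(occupancy, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(occupancy)) != 3L)
    stop("occupancy must be a 3D array, got ",
         length(dim(occupancy)), " dimensions")
  occ <- occupancy != 0
  dim(occ) <- dim(occupancy)
  new("VoxelMask", occupancy = occ, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Read a binary segmentation mask from a NIfTI-1 file
#'
#' Spacing is taken from the header pixel dimensions and the axis order
#' is mapped onto the package convention (slice, row, column). Any
#' nonzero voxel counts as occupied. Rotated orientation matrices are
#' rejected rather than resampled, since silent resampling changes
#' shape features; only axis-aligned (diagonal, up to sign) transforms
#' are accepted.
#'
#' @param path path to a .nii or .nii.gz file holding a 3D array.
#' @return a [VoxelMask]. An all-zero array yields an empty mask with a
#'   warning.
#' @export
readMask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (!is.null(d) && length(d) > 3L && all(d[-(1:3)] == 1L)) {
    dim(img) <- d[1:3]  # tolerate trailing singleton dims
    d <- dim(img)
  }
  if (is.null(d) || length(d) != 3L)
    stop("mask in ", path, " is not a 3D array (header field dim = ",
         paste(c(length(d), d), collapse = " "), ")")
  pd <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(pd)) || any(pd <= 0))
    stop("non-positive voxel spacing in header field pixdim of ", path,
         ": ", paste(pd, collapse = " "))
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6 * max(abs(diag(rot)), 1)))
    stop("mask ", path, " has a rotated orientation matrix; ",
         "resampling is refused because it changes shape features. ",
         "Provide axis-aligned data.")
  orig <- xf[1:3, 4]
  occ <- aperm(as.array(img) != 0, .AXPERM)
  if (!any(occ)) warning("mask ", path, " is empty (all-zero array)")
  new("VoxelMask", occupancy = occ, spacing = as.numeric(pd[.AXPERM]),
      origin = as.numeric(orig[.AXPERM]))
}

#' Write a mask to a NIfTI-1 file
#'
#' Re-reading the file with [readMask()] reproduces occupancy, spacing
#' and origin exactly.
#'
#' @param mask a [VoxelMask].
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "VoxelMask"))
  validObject(mask)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir)
  arr <- aperm(mask@occupancy, .AXPERM)
  storage.mode(arr) <- "integer"
  sp <- mask@spacing[.AXPERM]
  orig <- mask@origin[.AXPERM]
  img <- RNifti::asNifti(arr)
  m <- diag(c(sp, 1))
  m[1:3, 4] <- orig
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::`pixdim<-`(img, sp) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' The manifest is comma- or tab-delimited text with a header row and
#' columns `subject_id`, `group` (PTN/HC), `affected_side`
#' (left/right/none), `nvc_left`, `nvc_right` (yes/no), `mask_left`,
#' `mask_right` (file paths), plus optional `age` and `sex`. HC rows are
#' forced to affected side "none" (with a note when they carried
#' another value); structural violations are hard errors naming the
#' offending rows.
#'
#' @param path manifest file path.
#' @param checkPaths verify that every referenced mask path resolves
#'   (relative paths are resolved against the manifest's directory).
#' @return a [CohortManifest].
#' @export
readManifest <- function(path, checkPaths = TRUE) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, comment.char = "")
  miss <- setdiff(.manifestRequired, names(d))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "))
  hc <- d$group == "HC" & d$affected_side != "none"
  if (any(hc)) {
    message("forcing affected_side to 'none' for ", sum(hc), " HC row(s)")
    d$affected_side[hc] <- "none"
  }
  if (checkPaths) {
    base <- dirname(normalizePath(path))
    resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                  file.path(base, p))
    d$mask_left <- resolve(d$mask_left)
    d$mask_right <- resolve(d$mask_right)
    paths <- c(d$mask_left, d$mask_right)
    bad <- !file.exists(paths)
    if (any(bad))
      stop("unresolvable mask paths in manifest: ",
           paste(utils::head(paths[bad], 5), collapse = ", "),
           if (sum(bad) > 5) sprintf(" (and %d more)", sum(bad) - 5) else "")
  }
  new("CohortManifest", data = d)
}

#' Write a cohort manifest to CSV
#'
#' @param manifest a [CohortManifest].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "CohortManifest"))
  utils::write.csv(manifest@data, path, row.names = FALSE)
  invisible(path)
}
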