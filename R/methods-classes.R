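# Accessors and show() methods for the core classes.

#' @rdname VoxelMask-class
#' @export
setMethod("occupancy", "VoxelMask", function(x) x@occupancy)

#' @rdname VoxelMask-class
#' @export
setMethod("maskSpacing", "VoxelMask", function(x) x@spacing)

#' @rdname VoxelMask-class
#' @export
setMethod("maskOrigin", "VoxelMask", function(x) x@origin)

#' @rdname VoxelMask-class
#' @export
setMethod("nOccupied", "VoxelMask", function(x) sum(x@occupancy))

#' @rdname VoxelMask-class
#' @export
setMethod("isEmptyMask", "VoxelMask", function(x) !any(x@occupancy))

setMethod("show", "VoxelMask", function(object) {
  d <- dim(object@occupancy)
  cat("VoxelMask:", d[1], "x", d[2], "x", d[3], "(slice, row, column)\n")
  cat("  spacing (mm):", paste(signif(object@spacing, 4), collapse = " x "),
      " origin (mm):", paste(signif(object@origin, 4), collapse = ", "), "\n")
  n <- sum(object@occupancy)
  cat("  occupied voxels:", n,
      if (n == 0) "(empty)" else
        sprintf("(%.2f mm^3)", n * prod(object@spacing)), "\n")
})

#' @rdname SurfaceMesh-class
#' @export
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)

#' @rdname SurfaceMesh-class
#' @export
setMethod("meshTriangles", "SurfaceMesh", function(x) x@triangles)

setMethod("show", "SurfaceMesh", function(object) {
  cat("SurfaceMesh:", nrow(object@vertices), "vertices,",
      nrow(object@triangles), "triangles\n")
})

#' @rdname ShapeFeatures-class
#' @export
setMethod("featureValues", "ShapeFeatures", function(x) x@values)

setMethod("show", "ShapeFeatures", function(object) {
  cat("ShapeFeatures:\n")
  v <- object@values
  disp <- featureDisplayNames()
  for (nm in featureNames())
    cat(sprintf("  %-34s %s\n", disp[[nm]], signif(v[[nm]], 6)))
})

#' @describeIn ShapeFeatures-class one-row data.frame with canonical
#'   column names.
#' @param row.names,optional,... passed through (see
#'   [base::as.data.frame]).
#' @export
as.data.frame.ShapeFeatures <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  as.data.frame(as.list(x@values), row.names = row.names, ...)
}

#' @rdname CohortManifest-class
#' @export
setMethod("manifestData", "CohortManifest", function(x) x@data)

#' @rdname CohortManifest-class
#' @export
setMethod("nSubjects", "CohortManifest", function(x) nrow(x@data))

setMethod("show", "CohortManifest", function(object) {
  d <- object@data
  cat("CohortManifest:", nrow(d), "subjects (",
      sum(d$group == "PTN"), "PTN,", sum(d$group == "HC"), "HC )\n")
  if (any(d$group == "PTN"))
    cat("  affected side: left", sum(d$affected_side == "left"),
        "/ right", sum(d$affected_side == "right"), "\n")
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult: %s [%s%s]\n", object@contrast, object@test,
              if (object@paired) ", paired" else ""))
  cat(sprintf("  arm A: n=%d mean=%.4g sd=%.4g | arm B: n=%d mean=%.4g sd=%.4g\n",
              object@n[1], object@mean[1], object@sd[1],
              object@n[2], object@mean[2], object@sd[2]))
  if (nzchar(object@note)) cat("  flagged:", object@note, "\n")
  else cat(sprintf("  statistic=%.4g  p=%.4g\n", object@statistic, object@p))
})

#' @describeIn ComparisonResult-class one-row data.frame rendering.
#' @param x a `ComparisonResult`
#' @param row.names,optional,... see [base::as.data.frame].
#' @export
as.data.frame.ComparisonResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(contrast = x@contrast, test = x@test, paired = x@paired,
             n_a = x@n[1], mean_a = x@mean[1], sd_a = x@sd[1],
             n_b = x@n[2], mean_b = x@mean[2], sd_b = x@sd[2],
             statistic = x@statistic, p = x@p, note = x@note,
             row.names = row.names, ...)
}

# internal constructor used across the stats pipeline
.comparison <- function(contrast, test, nA, nB, meanA, sdA, meanB, sdB,
                        statistic = NA_real_, p = NA_real_,
                        paired = FALSE, note = "") {
  new("ComparisonResult", contrast = contrast, test = test,
      n = c(nA, nB), mean = c(meanA, meanB), sd = c(sdA, sdB),
      statistic = statistic, p = p, paired = paired, note = note)
}
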