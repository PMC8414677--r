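# The ten shape features: trivial identities, independent oracles, and
# the geometric invariants.

test_that("voxel volume is count times single-voxel volume", {
  one <- VoxelMask(array(c(1, rep(0, 7)), c(2, 2, 2)))
  expect_equal(voxelVolume(one), 1.0)

  block <- VoxelMask(array(TRUE, c(10, 10, 10)), spacing = c(0.5, 1, 1))
  expect_equal(voxelVolume(block), 500.0)

  expect_error(voxelVolume(VoxelMask(array(0, c(2, 2, 2)))), "empty ROI")
})

test_that("meshes are closed and free of degenerate triangles", {
  cases <- list(
    single = VoxelMask(array(c(rep(0, 13), 1, rep(0, 13)), c(3, 3, 3))),
    block = {
      occ <- array(FALSE, c(6, 6, 6)); occ[3:4, 3:4, 3:4] <- TRUE
      VoxelMask(occ)
    },
    sphere = sphereMask(5, 0.5))
  for (nm in names(cases)) {
    mesh <- buildSurfaceMesh(cases[[nm]])
    expect_gt(nrow(meshVertices(mesh)), 0)
    expect_true(all(edgeShareCounts(mesh) == 2), label = nm)
    v <- meshVertices(mesh); f <- meshTriangles(mesh)
    e1 <- v[f[, 2], ] - v[f[, 1], ]; e2 <- v[f[, 3], ] - v[f[, 1], ]
    areas <- 0.5 * sqrt(rowSums(cbind(
      e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
      e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
      e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2))
    expect_gt(min(areas), 1e-12)
    expect_gt(surfaceArea(mesh), 0)
  }
})

test_that("surface area matches hand-built triangles and a Heron oracle", {
  tri <- new("SurfaceMesh",
             vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
             triangles = matrix(c(1L, 2L, 3L), 1))
  expect_equal(surfaceArea(tri), 0.5)

  square <- new("SurfaceMesh",
                vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                 c(0, 1, 0)),
                triangles = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  expect_equal(surfaceArea(square), 1.0)

  mesh <- buildSurfaceMesh(makePhantom(c(6, 4, 3), rotation = c(0.4, 0.2, 0.9),
                                       spacing = 0.5))
  expect_equal(surfaceArea(mesh), heronArea(mesh), tolerance = 1e-9)
})

test_that("Feret diameters match trivial cases and the brute-force oracle", {
  two <- new("SurfaceMesh", vertices = rbind(c(0, 0, 0), c(3, 4, 0)),
             triangles = matrix(integer(0), 0, 3))
  expect_equal(maxDiameter3D(two), 5.0)

  pts <- new("SurfaceMesh", vertices = rbind(c(0, 0, 0), c(7, 3, 4)),
             triangles = matrix(integer(0), 0, 3))
  expect_equal(maxDiameter2D(pts, "slice"), 5.0)   # drop first axis

  mesh <- buildSurfaceMesh(makePhantom(c(5, 4, 2), rotation = c(1, 0.3, 0.7),
                                       spacing = 0.6, boundaryNoiseSd = 0.2,
                                       seed = 3))
  v <- meshVertices(mesh)
  expect_lte(nrow(v), 5000)
  expect_equal(maxDiameter3D(mesh), bruteMaxDist(v), tolerance = 1e-12)
  expect_equal(maxDiameter2D(mesh, "slice"), bruteMaxDist(v, 2:3),
               tolerance = 1e-12)
  expect_equal(maxDiameter2D(mesh, "column"), bruteMaxDist(v, 1:2),
               tolerance = 1e-12)
  expect_equal(maxDiameter2D(mesh, "row"), bruteMaxDist(v, c(1, 3)),
               tolerance = 1e-12)

  single <- new("SurfaceMesh", vertices = matrix(0, 1, 3),
                triangles = matrix(integer(0), 0, 3))
  expect_error(maxDiameter3D(single), "2 vertices")
  expect_error(maxDiameter2D(mesh, "axial"), "plane")
})

test_that("axis lengths recover the uniform-ellipsoid closed form", {
  m <- makePhantom(c(20, 12, 8), spacing = 0.5)
  ax <- axisLengths(m)
  expect_equal(ax$major, 4 * 20 / sqrt(5), tolerance = 0.01)
  expect_equal(ax$minor, 4 * 12 / sqrt(5), tolerance = 0.01)
  expect_equal(ax$least, 4 * 8 / sqrt(5), tolerance = 0.01)
  expect_true(ax$major >= ax$minor && ax$minor >= ax$least)
})

test_that("planar and point masks degenerate to zero least axis and flatness", {
  occ <- array(FALSE, c(5, 9, 9))
  g <- seq(-4, 4)
  occ[3, , ] <- outer(g^2, g^2, "+") <= 16  # single-slice disc
  disc <- VoxelMask(occ)
  ax <- axisLengths(disc)
  expect_equal(ax$least, 0)
  expect_equal(flatnessFromEigenvalues(ax$eigenvalues), 0)

  one <- VoxelMask(array(c(1, rep(0, 26)), c(3, 3, 3)))
  expect_warning(ax1 <- axisLengths(one), "single-voxel")
  expect_equal(unlist(ax1[c("major", "minor", "least")]),
               c(major = 0, minor = 0, least = 0))
})

test_that("flatness handles spheres, degenerate and invalid eigenvalues", {
  expect_equal(flatnessFromEigenvalues(c(2, 2, 2)), 1.0)
  expect_warning(fl <- flatnessFromEigenvalues(c(0, 0, 0)), "undefined")
  expect_true(is.na(fl))
  expect_error(flatnessFromEigenvalues(c(4, 1, -0.5)), "negative")
  # numerical-noise clamp below the tolerance
  expect_equal(flatnessFromEigenvalues(c(4, 1, -1e-13)), 0)
})

test_that("extractFeatures satisfies the cross-feature invariants", {
  for (m in list(makePhantom(c(5, 4, 2), rotation = c(0.5, 1.1, 0.2),
                             spacing = 0.5),
                 makePhantom(c(6, 5, 5), spacing = 0.7,
                             boundaryNoiseSd = 0.3, seed = 9))) {
    v <- featureValues(extractFeatures(m))
    expect_true(all(v >= 0))
    expect_gte(v[["major_axis_length"]], v[["minor_axis_length"]])
    expect_gte(v[["minor_axis_length"]], v[["least_axis_length"]])
    d2 <- v[c("max_2d_diameter_slice", "max_2d_diameter_column",
              "max_2d_diameter_row")]
    expect_gte(v[["max_3d_diameter"]], max(d2))
    expect_lte(v[["flatness"]], 1)
  }
})

test_that("features are translation invariant and flatness scale invariant", {
  occ <- occupancy(makePhantom(c(4, 3, 2), spacing = 0.5))
  a <- featureValues(extractFeatures(VoxelMask(occ, c(0.5, 0.5, 0.5),
                                               origin = c(0, 0, 0))))
  b <- featureValues(extractFeatures(VoxelMask(occ, c(0.5, 0.5, 0.5),
                                               origin = c(11, -4, 2.5))))
  expect_equal(a, b, tolerance = 1e-10)

  # doubling the spacing doubles lengths but leaves flatness unchanged
  s2 <- featureValues(extractFeatures(VoxelMask(occ, c(1, 1, 1))))
  expect_equal(s2[["flatness"]], a[["flatness"]], tolerance = 1e-10)
  expect_equal(s2[["major_axis_length"]], 2 * a[["major_axis_length"]],
               tolerance = 1e-10)
  expect_equal(s2[["voxel_volume"]], 8 * a[["voxel_volume"]])
})

test_that("ellipsoid flatness error shrinks monotonically with spacing", {
  errs <- vapply(c(1.0, 0.5, 0.25), function(sp) {
    ax <- axisLengths(makePhantom(c(8, 5, 3.2), spacing = sp))
    abs(flatnessFromEigenvalues(ax$eigenvalues) - 3.2 / 8)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.004)
})
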