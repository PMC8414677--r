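# Synthetic bilateral cohorts of Meckel-cave-like masks. Phantoms are
# solid rotated ellipsoids discretized on a regular grid; flatness is
# controlled through the least/major semi-axis ratio c/a (the continuum
# identity flatness = c/a) and volume through abc scaling. Ground truth
# for every drawn parameter is recorded, so downstream statistics can be
# validated against known effects.

.rotationMatrix <- function(angles) {
  # intrinsic Z-Y-X Euler rotation
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

#' Generate a solid (optionally noised) ellipsoidal phantom mask
#'
#' Discretizes a rotated solid ellipsoid with semi-axes `semiAxes`
#' (mm, sorted descending internally) on a grid with the requested
#' spacing and at least `marginVoxels` empty voxels on every side. An
#' optional smooth angular perturbation of the boundary radius with
#' standard deviation `boundaryNoiseSd` (mm) roughens the surface;
#' the draw is deterministic given `seed`.
#'
#' @param semiAxes numeric(3), semi-axis lengths a >= b >= c in mm (any
#'   order accepted, sorted internally).
#' @param rotation numeric(3) Euler angles (rad), intrinsic Z-Y-X.
#' @param spacing numeric(3) or scalar voxel spacing in mm.
#' @param boundaryNoiseSd radial boundary perturbation sd in mm (>= 0).
#' @param seed integer seed for the boundary noise (ignored when
#'   `boundaryNoiseSd` is 0).
#' @param marginVoxels empty margin on each side, in voxels (>= 2).
#' @param maxGridVoxels safety cap on total grid size.
#' @return a [VoxelMask].
#' @export
makePhantom <- function(semiAxes, rotation = c(0, 0, 0),
                        spacing = c(0.5, 0.5, 0.5), boundaryNoiseSd = 0,
                        seed = 1L, marginVoxels = 2L,
                        maxGridVoxels = 3e7) {
  stopifnot(length(semiAxes) == 3, all(semiAxes > 0), boundaryNoiseSd >= 0)
  ax <- sort(as.numeric(semiAxes), decreasing = TRUE)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  stopifnot(all(spacing > 0))
  R <- .rotationMatrix(rotation)
  # half-extent of the rotated ellipsoid along each grid axis
  RD <- R %*% diag(ax)
  halfext <- sqrt(rowSums(RD^2)) + 4 * boundaryNoiseSd
  dims <- as.integer(ceiling(2 * halfext / spacing)) + 2L * marginVoxels + 1L
  if (prod(dims) > maxGridVoxels)
    stop("phantom grid would need ", paste(dims, collapse = "x"),
         " voxels (> maxGridVoxels); increase spacing or the cap")
  ctr <- (dims - 1) / 2 * spacing
  g1 <- (seq_len(dims[1]) - 1) * spacing[1] - ctr[1]
  g2 <- (seq_len(dims[2]) - 1) * spacing[2] - ctr[2]
  g3 <- (seq_len(dims[3]) - 1) * spacing[3] - ctr[3]
  # centered coordinates of all voxels, rotated into ellipsoid frame
  X1 <- rep(g1, times = dims[2] * dims[3])
  X2 <- rep(rep(g2, each = dims[1]), times = dims[3])
  X3 <- rep(g3, each = dims[1] * dims[2])
  B1 <- R[1, 1] * X1 + R[2, 1] * X2 + R[3, 1] * X3
  B2 <- R[1, 2] * X1 + R[2, 2] * X2 + R[3, 2] * X3
  B3 <- R[1, 3] * X1 + R[2, 3] * X2 + R[3, 3] * X3
  rho <- sqrt((B1 / ax[1])^2 + (B2 / ax[2])^2 + (B3 / ax[3])^2)
  if (boundaryNoiseSd > 0) {
    # smooth zero-mean angular field: random low-order directional
    # harmonics, normalized to unit sd over the sampled directions
    set.seed(as.integer(seed %% 2147483647))
    K <- 8L
    dirs <- matrix(stats::rnorm(3 * K), K, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    w <- stats::rnorm(K)
    rn <- pmax(sqrt(X1^2 + X2^2 + X3^2), 1e-9)
    u1 <- X1 / rn; u2 <- X2 / rn; u3 <- X3 / rn
    g <- 0
    for (k in seq_len(K))
      g <- g + w[k] * (dirs[k, 1] * u1 + dirs[k, 2] * u2 + dirs[k, 3] * u3)^3
    g <- g / max(stats::sd(g), 1e-12) * boundaryNoiseSd
    # perturb the boundary radius by g mm along each direction; the
    # local ellipsoid radius along direction u is 1/||D^-1 R^T u||
    ru <- 1 / pmax(sqrt((R[1, 1] * u1 + R[2, 1] * u2 + R[3, 1] * u3)^2 / ax[1]^2 +
                        (R[1, 2] * u1 + R[2, 2] * u2 + R[3, 2] * u3)^2 / ax[2]^2 +
                        (R[1, 3] * u1 + R[2, 3] * u2 + R[3, 3] * u3)^2 / ax[3]^2),
                   1e-9)
    occ <- rho <= 1 + g / ru
  } else {
    occ <- rho <= 1
  }
  dim(occ) <- dims
  if (!any(occ))
    stop("grid too small for the ellipsoid: no voxel center fell inside; ",
         "required extent >= ", paste(signif(2 * halfext, 3), collapse = "x"),
         " mm")
  new("VoxelMask", occupancy = occ, spacing = spacing, origin = c(0, 0, 0))
}

# Semi-axes (a, b, c) realizing a target volume (mm^3) and flatness
# f = c/a, with fixed middle-axis ratio b = bOverA * a:
# V = 4/3 pi a^3 * bOverA * f.
.semiAxesFor <- function(volume, flatness, bOverA = 0.8) {
  a <- (3 * volume / (4 * pi * bOverA * flatness))^(1 / 3)
  c(a, bOverA * a, flatness * a)
}

#' Default neurovascular-contact pattern probabilities
#'
#' Frequencies of the four (affected-side NVC, unaffected-side NVC)
#' patterns among left- and right-affected patients, as reported for
#' the study cohort the generator emulates.
#'
#' @return list with `left` and `right`, each a named numeric(4)
#'   distribution over patterns "yes_no", "no_yes", "yes_yes", "no_no".
#' @export
defaultNvcProbabilities <- function() {
  list(left = c(yes_no = 12, no_yes = 4, yes_yes = 13, no_no = 9) / 38,
       right = c(yes_no = 34, no_yes = 9, yes_yes = 25, no_no = 9) / 77)
}

# independent per-subject substream so adding subjects never perturbs
# earlier ones
.subjectSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i * 7919) %% 2147483629)
}

#' Simulate a bilateral cohort of Meckel-cave-like phantoms
#'
#' Each subject gets a left and a right mask. Per-side target flatness
#' is side mean, minus `affectedFlatnessDelta` on the affected side,
#' plus a shared per-subject deviation (sd `betweenSubjectSd`) and an
#' independent per-side deviation (sd `withinSubjectSd`); infeasible
#' draws are redrawn (cap 100, then error). Volumes are log-uniform in
#' `volumeRange` with within-subject Gaussian-copula correlation
#' `volumeCorrelation`. The affected side of each patient is Bernoulli
#' (`pRightAffected`); NVC patterns are drawn from `nvcProbabilities`
#' (healthy controls are recorded as no/no). Ages and sexes are drawn
#' per group so the demographics table can be exercised. Everything is
#' reproducible from `seed`, with one counter-based substream per
#' subject.
#'
#' @param nPtn,nHc numbers of patients and healthy controls.
#' @param pRightAffected probability the affected side is the right.
#' @param flatnessMeanLeft,flatnessMeanRight side-specific flatness
#'   means (defaults match the emulated study's left/right values).
#' @param affectedFlatnessDelta flatness subtracted on the affected
#'   side.
#' @param betweenSubjectSd sd of the per-subject (shared across sides)
#'   flatness deviation.
#' @param withinSubjectSd sd of the independent per-side deviation.
#' @param nvcProbabilities see [defaultNvcProbabilities()].
#' @param volumeRange mm^3 range of target volumes (log-uniform).
#' @param volumeCorrelation within-subject correlation of log-volumes.
#' @param bOverA middle/major semi-axis ratio of the phantoms.
#' @param spacing voxel spacing in mm (scalar or numeric(3)).
#' @param boundaryNoiseSd per-mask surface roughening in mm.
#' @param randomOrientation draw uniform random Euler angles per mask.
#' @param seed integer master seed.
#' @param outDir when non-NULL, NIfTI masks plus `manifest.csv` and
#'   `truth.csv` are written there and the manifest references the
#'   files; otherwise masks stay in memory.
#' @return list with `manifest` ([CohortManifest]), `masks` (named list
#'   of [VoxelMask], names `<id>_left` / `<id>_right`; NULL when
#'   written to disk with `keepMasks = FALSE`), and `truth`
#'   (data.frame of every drawn parameter).
#' @param keepMasks keep the masks in memory even when writing to disk.
#' @export
makeCohort <- function(nPtn = 115, nHc = 46,
                       pRightAffected = 77 / 115,
                       flatnessMeanLeft = 0.41, flatnessMeanRight = 0.39,
                       affectedFlatnessDelta = 0.02,
                       betweenSubjectSd = 0.04, withinSubjectSd = 0.03,
                       nvcProbabilities = defaultNvcProbabilities(),
                       volumeRange = c(94.23, 1589.90),
                       volumeCorrelation = 0.5,
                       bOverA = 0.8, spacing = 0.5,
                       boundaryNoiseSd = 0, randomOrientation = TRUE,
                       seed = 1L, outDir = NULL, keepMasks = TRUE) {
  stopifnot(nPtn >= 0, nHc >= 0, nPtn + nHc > 0,
            pRightAffected >= 0, pRightAffected <= 1,
            betweenSubjectSd >= 0, withinSubjectSd >= 0,
            length(volumeRange) == 2, all(volumeRange > 0),
            volumeCorrelation >= -1, volumeCorrelation <= 1,
            bOverA > 0, bOverA <= 1)
  for (side in c("left", "right")) {
    p <- nvcProbabilities[[side]]
    stopifnot(length(p) == 4, all(p >= 0), abs(sum(p) - 1) < 1e-6)
  }
  for (m in c(flatnessMeanLeft, flatnessMeanRight))
    if (m - affectedFlatnessDelta <= 0 || m >= 1)
      stop("flatness mean minus delta must stay in (0, 1)")
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)

  n <- nPtn + nHc
  ids <- sprintf("S%03d", seq_len(n))
  groups <- c(rep("PTN", nPtn), rep("HC", nHc))
  patterns <- c("yes_no", "no_yes", "yes_yes", "no_no")
  sideMean <- c(left = flatnessMeanLeft, right = flatnessMeanRight)

  rows <- vector("list", n)
  masks <- if (keepMasks || is.null(outDir)) list() else NULL
  truth <- vector("list", 2L * n)

  for (i in seq_len(n)) {
    set.seed(.subjectSeed(seed, i))
    grp <- groups[i]
    affected <- if (grp == "PTN") {
      if (stats::runif(1) < pRightAffected) "right" else "left"
    } else "none"
    # NVC pattern (affected NVC, unaffected NVC)
    if (grp == "PTN") {
      pat <- sample(patterns, 1, prob = nvcProbabilities[[affected]])
      aff_nvc <- if (pat %in% c("yes_no", "yes_yes")) "yes" else "no"
      una_nvc <- if (pat %in% c("no_yes", "yes_yes")) "yes" else "no"
      nvc <- if (affected == "left") c(aff_nvc, una_nvc) else c(una_nvc, aff_nvc)
    } else nvc <- c("no", "no")
    # demographics (means/sds of the emulated study's two groups)
    age <- if (grp == "PTN") stats::rnorm(1, 62.89, 10.43) else
      stats::rnorm(1, 49.28, 10.96)
    sex <- if (grp == "PTN") {
      if (stats::runif(1) < 70 / 115) "female" else "male"
    } else if (stats::runif(1) < 31 / 46) "female" else "male"
    # correlated log-volumes via Gaussian copula
    z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
    zr <- volumeCorrelation * z1 + sqrt(1 - volumeCorrelation^2) * z2
    lv <- log(volumeRange)
    vols <- exp(lv[1] + stats::pnorm(c(z1, zr)) * diff(lv))
    names(vols) <- c("left", "right")
    shared <- stats::rnorm(1, 0, betweenSubjectSd)

    subjMasks <- list()
    for (side in c("left", "right")) {
      ok <- FALSE
      for (attempt in seq_len(100)) {
        f <- sideMean[[side]] -
          (if (affected == side) affectedFlatnessDelta else 0) +
          shared + stats::rnorm(1, 0, withinSubjectSd)
        if (f > 0.02 && f < bOverA) { ok <- TRUE; break }
      }
      if (!ok) stop("infeasible flatness draw for subject ", ids[i],
                    " side ", side, " after 100 attempts")
      axs <- .semiAxesFor(vols[[side]], f, bOverA)
      rot <- if (randomOrientation) stats::runif(3, 0, pi) else c(0, 0, 0)
      m <- makePhantom(axs, rotation = rot, spacing = spacing,
                       boundaryNoiseSd = boundaryNoiseSd,
                       seed = .subjectSeed(seed, i) %% 2147480009 + 1)
      subjMasks[[side]] <- m
      truth[[2L * (i - 1L) + (side == "right") + 1L]] <- data.frame(
        subject_id = ids[i], side = side, group = grp,
        affected = (affected == side),
        target_flatness = f, target_volume = vols[[side]],
        semi_a = axs[1], semi_b = axs[2], semi_c = axs[3],
        rot_1 = rot[1], rot_2 = rot[2], rot_3 = rot[3])
    }

    if (is.null(outDir)) {
      keyL <- paste0(ids[i], "_left"); keyR <- paste0(ids[i], "_right")
      masks[[keyL]] <- subjMasks$left
      masks[[keyR]] <- subjMasks$right
      pathL <- paste0("memory:", keyL); pathR <- paste0("memory:", keyR)
    } else {
      pathL <- file.path(outDir, paste0(ids[i], "_left.nii.gz"))
      pathR <- file.path(outDir, paste0(ids[i], "_right.nii.gz"))
      writeMask(subjMasks$left, pathL)
      writeMask(subjMasks$right, pathR)
      if (keepMasks) {
        masks[[paste0(ids[i], "_left")]] <- subjMasks$left
        masks[[paste0(ids[i], "_right")]] <- subjMasks$right
      }
    }
    rows[[i]] <- data.frame(
      subject_id = ids[i], group = grp, affected_side = affected,
      nvc_left = nvc[1], nvc_right = nvc[2],
      mask_left = pathL, mask_right = pathR,
      age = age, sex = sex)
  }

  manifest <- new("CohortManifest", data = do.call(rbind, rows))
  truthDf <- do.call(rbind, truth)
  if (!is.null(outDir)) {
    writeManifest(manifest, file.path(outDir, "manifest.csv"))
    utils::write.csv(truthDf, file.path(outDir, "truth.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, masks = masks, truth = truthDf)
}

#' Extract shape features for every mask of a cohort
#'
#' @param cohort a list as returned by [makeCohort()], or a
#'   [CohortManifest] whose mask paths resolve on disk.
#' @param mesh compute the mesh-based features (surface area, Feret
#'   diameters)? With `FALSE` only the grid-based features (volume,
#'   axis lengths, flatness) are filled, which is much faster for large
#'   simulation studies.
#' @param smoothingSigma passed to [buildSurfaceMesh()].
#' @return data.frame with columns subject_id, side and the ten feature
#'   columns (mesh features NA when `mesh = FALSE`).
#' @export
extractCohortFeatures <- function(cohort, mesh = TRUE, smoothingSigma = 1) {
  if (is(cohort, "CohortManifest"))
    cohort <- list(manifest = cohort, masks = NULL)
  d <- manifestData(cohort$manifest)
  out <- vector("list", 2L * nrow(d))
  for (i in seq_len(nrow(d))) {
    for (side in c("left", "right")) {
      path <- d[[paste0("mask_", side)]][i]
      m <- if (startsWith(path, "memory:"))
        cohort$masks[[sub("^memory:", "", path)]]
      else readMask(path)
      if (is.null(m)) stop("mask not found for ", d$subject_id[i], " ", side)
      if (mesh) {
        fv <- featureValues(extractFeatures(m, smoothingSigma))
      } else {
        ax <- withCallingHandlers(axisLengths(m),
          warning = function(w) invokeRestart("muffleWarning"))
        fv <- stats::setNames(rep(NA_real_, 10L), featureNames())
        fv["voxel_volume"] <- voxelVolume(m)
        fv["minor_axis_length"] <- ax$minor
        fv["major_axis_length"] <- ax$major
        fv["least_axis_length"] <- ax$least
        fv["flatness"] <- if (max(ax$eigenvalues) == 0) 0 else
          flatnessFromEigenvalues(ax$eigenvalues)
      }
      out[[2L * (i - 1L) + (side == "right") + 1L]] <-
        cbind(data.frame(subject_id = d$subject_id[i], side = side),
              as.data.frame(as.list(fv)))
    }
  }
  do.call(rbind, out)
}
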