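# In-code fixtures and independent oracles shared across tests.

# axis-aligned solid sphere mask built directly from the grid equation
# (independent of makePhantom)
sphereMask <- function(r = 10, spacing = 0.5, margin = 3L) {
  n <- as.integer(ceiling(2 * r / spacing)) + 2L * margin
  ctr <- (n - 1) / 2
  g <- ((seq_len(n) - 1) - ctr) * spacing
  d2 <- outer(outer(g^2, g^2, "+"), g^2, "+")
  VoxelMask(array(d2 <= r^2, c(n, n, n)), spacing = rep(spacing, 3))
}

# every undirected edge of a closed mesh is shared by exactly two
# triangles
edgeShareCounts <- function(mesh) {
  f <- meshTriangles(mesh)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  table(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

# Heron's-formula triangle-area oracle, independent of the
# cross-product implementation in surfaceArea()
heronArea <- function(mesh) {
  v <- meshVertices(mesh); f <- meshTriangles(mesh)
  elen <- function(i, j) sqrt(rowSums((v[f[, i], , drop = FALSE] -
                                       v[f[, j], , drop = FALSE])^2))
  a <- elen(1, 2); b <- elen(2, 3); c <- elen(3, 1)
  s <- (a + b + c) / 2
  sum(sqrt(pmax(s * (s - a) * (s - b) * (s - c), 0)))
}

# O(n^2) all-pairs maximum distance oracle in plain R
bruteMaxDist <- function(pts, cols = seq_len(ncol(pts))) {
  max(stats::dist(pts[, cols, drop = FALSE]))
}

# brute-force tie-corrected Kendall tau-b by pair enumeration
bruteTauB <- function(x, y) {
  n <- length(x); C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    if (x[i] == x[j]) tx <- tx + 1
    if (y[i] == y[j]) ty <- ty + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# minimal hand-built manifest data.frame
makeManifestDf <- function(n_ptn = 2, n_hc = 1, maskPath = "x.nii") {
  n <- n_ptn + n_hc
  data.frame(
    subject_id = sprintf("T%02d", seq_len(n)),
    group = c(rep("PTN", n_ptn), rep("HC", n_hc)),
    affected_side = c(rep(c("left", "right"), length.out = n_ptn),
                      rep("none", n_hc)),
    nvc_left = "no", nvc_right = "no",
    mask_left = maskPath, mask_right = maskPath,
    stringsAsFactors = FALSE)
}
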