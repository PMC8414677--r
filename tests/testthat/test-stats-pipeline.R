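# The statistical battery against enumeration oracles, reference
# implementations and structural invariants.

# small deterministic subject table with controllable feature values
toySubjectTable <- function(nPtn = 10, nHc = 4, seed = 1,
                            deltaFlatness = 0) {
  set.seed(seed)
  man <- new("CohortManifest", data = makeManifestDf(nPtn, nHc))
  d <- manifestData(man)
  rows <- lapply(seq_len(nrow(d)), function(i) {
    out <- lapply(c("left", "right"), function(side) {
      f <- stats::setNames(as.list(abs(stats::rnorm(10, 10, 2))),
                           featureNames())
      f$flatness <- stats::runif(1, 0.3, 0.5) -
        if (d$affected_side[i] == side) deltaFlatness else 0
      cbind(data.frame(subject_id = d$subject_id[i], side = side),
            as.data.frame(f))
    })
    do.call(rbind, out)
  })
  list(manifest = man, features = do.call(rbind, rows))
}

test_that("exact binomial laterality test matches closed-form cases", {
  r <- binomialLateralityTest(38, 77)
  expect_equal(r@mean, c(100 * 38 / 115, 100 * 77 / 115))
  expect_equal(r@p, stats::binom.test(77, 115)$p.value)
  expect_lt(r@p, 0.01)

  expect_equal(binomialLateralityTest(10, 10)@p, 1.0)
  expect_equal(binomialLateralityTest(0, 8)@p, 2 * 0.5^8)  # 0.0078125
  expect_error(binomialLateralityTest(0, 0), "zero")
})

test_that("paired side comparison agrees with stats::t.test and flags
           degenerate strata", {
  toy <- toySubjectTable(nPtn = 12, nHc = 3, seed = 7)
  tab <- buildSubjectTable(toy$manifest, toy$features)
  cr <- pairedSideComparison(tab, "flatness", "left_right", "PTN")
  l <- tab$flatness[tab$group == "PTN" & tab$side == "left"]
  r <- tab$flatness[tab$group == "PTN" & tab$side == "right"]
  ref <- stats::t.test(l, r, paired = TRUE)
  expect_equal(cr@p, ref$p.value, tolerance = 1e-12)
  expect_equal(cr@statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_true(cr@paired)

  # identical sides: zero within-pair variance is flagged, not tested
  tied <- toy
  tied$features$flatness <- 0.4
  tabT <- buildSubjectTable(tied$manifest, tied$features)
  crT <- pairedSideComparison(tabT, "flatness", "left_right", "PTN")
  expect_true(is.na(crT@p))
  expect_match(crT@note, "zero within-pair variance")

  # too-small stratum flagged
  toy2 <- toySubjectTable(nPtn = 2, nHc = 0)
  tab2 <- buildSubjectTable(toy2$manifest, toy2$features)
  cr2 <- pairedSideComparison(tab2, "flatness", "affected_unaffected")
  expect_true(is.na(cr2@p))
  expect_match(cr2@note, "too small")
})

test_that("OLS group comparison equals the pooled t-test identity", {
  toy <- toySubjectTable(nPtn = 10, nHc = 8, seed = 42)
  tab <- buildSubjectTable(toy$manifest, toy$features)
  armA <- tab$group == "HC"
  armB <- tab$group == "PTN" & tab$affected
  cr <- groupComparison(tab, "surface_area", armA, armB)
  ref <- stats::t.test(tab$surface_area[armA], tab$surface_area[armB],
                       var.equal = TRUE)
  expect_equal(abs(cr@statistic), abs(unname(ref$statistic)),
               tolerance = 1e-9)
  expect_equal(cr@p, ref$p.value, tolerance = 1e-9)

  crW <- groupComparison(tab, "surface_area", armA, armB, welch = TRUE)
  refW <- stats::t.test(tab$surface_area[armA], tab$surface_area[armB])
  expect_equal(crW@p, refW$p.value, tolerance = 1e-12)

  # identical values in both arms: zero coefficient, p = 1
  tab$voxel_volume[] <- 7
  cr0 <- groupComparison(tab, "voxel_volume", armA, armB)
  expect_equal(cr0@statistic, 0)
  expect_equal(cr0@p, 1)

  expect_error(groupComparison(tab, "flatness", armA, armA), "disjoint")
})

test_that("Kendall screen is tau-b (tie-corrected) and ranks |tau|", {
  # enumeration oracle on the documented 5-point example
  expect_equal(bruteTauB(1:5, c(3, 1, 2, 5, 4)), 0.4)
  expect_equal(stats::cor(1:5, c(3, 1, 2, 5, 4), method = "kendall"), 0.4)
  # ties: implementation equals the enumeration oracle
  set.seed(5)
  x <- sample(1:4, 30, replace = TRUE)
  y <- sample(1:5, 30, replace = TRUE)
  expect_equal(stats::cor(x, y, method = "kendall"), bruteTauB(x, y),
               tolerance = 1e-12)

  toy <- toySubjectTable(nPtn = 15, nHc = 6, seed = 3)
  # make least axis a noisy monotone function of flatness and the major
  # axis antitone, mirroring the geometry
  toy$features$least_axis_length <- 5 * toy$features$flatness +
    stats::rnorm(nrow(toy$features), 0, 0.1)
  toy$features$major_axis_length <- 10 - 5 * toy$features$flatness +
    stats::rnorm(nrow(toy$features), 0, 0.1)
  tab <- buildSubjectTable(toy$manifest, toy$features)
  sc <- kendallCorrelationScreen(tab, "PTN")
  expect_equal(nrow(sc), 9)
  expect_gt(sc$tau[sc$feature == "least_axis_length"], 0)
  expect_lt(sc$tau[sc$feature == "major_axis_length"], 0)
  expect_true(!is.unsorted(rev(abs(sc$tau))))

  # perfectly monotone pair
  toy$features$surface_area <- toy$features$flatness^3
  tab <- buildSubjectTable(toy$manifest, toy$features)
  sc <- kendallCorrelationScreen(tab, "PTN")
  expect_equal(sc$tau[sc$feature == "surface_area"], 1.0)

  # tau-b invariant under monotone transform of a feature
  t1 <- kendallCorrelationScreen(tab, "PTN")
  toy$features$voxel_volume <- exp(toy$features$voxel_volume / 10)
  t2 <- kendallCorrelationScreen(
    buildSubjectTable(toy$manifest, toy$features), "PTN")
  expect_equal(t2$tau[t2$feature == "voxel_volume"],
               t1$tau[t1$feature == "voxel_volume"], tolerance = 1e-12)

  # constant feature flagged
  toy$features$minor_axis_length <- 1
  sc3 <- kendallCorrelationScreen(
    buildSubjectTable(toy$manifest, toy$features), "PTN")
  expect_true(is.na(sc3$tau[sc3$feature == "minor_axis_length"]))
})

test_that("demographics table reproduces count-derived percentages", {
  man <- new("CohortManifest",
             data = makeManifestDf(115, 46))
  d <- manifestData(man)
  d$affected_side[d$group == "PTN"] <- rep(c("left", "right"),
                                           c(38, 77))
  man <- new("CohortManifest", data = d)
  sexes <- c(rep(c("male", "female"), c(45, 70)),
             rep(c("male", "female"), c(15, 31)))
  ages <- c(stats::rnorm(115, 63, 10), stats::rnorm(46, 49, 11))
  t1 <- demographicsTable(man, ages = ages, sexes = sexes)
  expect_equal(t1$ptn_pct[t1$row == "male"], 39.13)
  expect_equal(t1$ptn_pct[t1$row == "female"], 60.87)
  expect_equal(t1$hc_pct[t1$row == "male"], 32.61)   # 15/46, exact 2 dp
  expect_equal(t1$hc_pct[t1$row == "female"], 67.39)
  expect_equal(t1$ptn_pct[t1$row == "case_number"], 71.43)
  # within-group percentages sum to 100
  expect_equal(t1$ptn_pct[t1$row == "male"] +
                 t1$ptn_pct[t1$row == "female"], 100, tolerance = 0.1)

  # symmetric 2x2 gives chi-square statistic 0 / p 1 without correction
  sex0 <- rep(c("male", "female"), 20)
  man0 <- new("CohortManifest", data = makeManifestDf(20, 20))
  t0 <- demographicsTable(man0, sexes = sex0,
                          ages = stats::rnorm(40, 50, 5))
  expect_equal(t0$p[t0$row == "male"], 1)

  # missing covariates flag rows instead of erroring
  tm <- demographicsTable(man0)
  expect_true(any(tm$test == "missing covariate"))
})

test_that("NVC cross-tab reproduces printed-count percentages", {
  n <- 38
  d <- makeManifestDf(n, 0)
  d$affected_side <- "left"
  pats <- rep(c("yes_no", "no_yes", "yes_yes", "no_no"),
              c(12, 4, 13, 9))
  d$nvc_left <- ifelse(pats %in% c("yes_no", "yes_yes"), "yes", "no")
  d$nvc_right <- ifelse(pats %in% c("no_yes", "yes_yes"), "yes", "no")
  man <- new("CohortManifest", data = d)
  ct <- nvcCrosstab(man)
  left <- ct[ct$affected_side == "left", ]
  expect_equal(left$n, c(12L, 4L, 13L, 9L))
  expect_equal(left$pct, c(31.6, 10.5, 34.2, 23.7))
  expect_equal(sum(left$pct), 100, tolerance = 0.1)

  # single record: one cell at 100%
  d1 <- makeManifestDf(1, 0)
  d1$affected_side <- "right"
  ct1 <- nvcCrosstab(new("CohortManifest", data = d1))
  expect_equal(max(ct1$pct[ct1$affected_side == "right"]), 100)
})

test_that("no-NVC subgroup comparison isolates an injected flatness
           deficit and stays null at delta 0", {
  mk <- function(delta, seed) {
    coh <- makeCohort(nPtn = 40, nHc = 0, affectedFlatnessDelta = delta,
                      flatnessMeanLeft = 0.4, flatnessMeanRight = 0.4,
                      withinSubjectSd = 0.01, spacing = 1.0, seed = seed)
    feats <- extractCohortFeatures(coh, mesh = FALSE)
    tab <- buildSubjectTable(coh$manifest, feats)
    noNvcSubgroupComparison(tab)
  }
  t4 <- mk(0.05, 31)
  fl <- t4[t4$feature == "flatness" & !nzchar(t4$note), ]
  # affected mean below unaffected in every testable stratum
  expect_true(all(fl$mean_a < fl$mean_b))

  t40 <- mk(0, 32)
  fl0 <- t40[t40$feature == "flatness" & !nzchar(t40$note), ]
  expect_true(all(abs(fl0$mean_a - fl0$mean_b) < 0.02))
  expect_equal(sort(unique(t4$affected_side)), c("left", "right"))
  expect_equal(nrow(t4), 20)
})

test_that("runFullAnalysis emits the four tables deterministically", {
  coh <- makeCohort(nPtn = 20, nHc = 8, seed = 12, spacing = 1.0)
  feats <- extractCohortFeatures(coh, mesh = TRUE)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- runFullAnalysis(coh$manifest, feats, outDir = d1, seed = 12)
  r2 <- runFullAnalysis(coh$manifest, feats, outDir = d2, seed = 12)
  for (f in c("table1.csv", "table2.csv", "table3.csv", "table4.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_equal(nrow(r1$table2), 10)
  expect_true(all(c("hc_vs_ptn_affected_p", "ptn_affected_vs_unaffected_p",
                    "ptn_left_vs_right_p", "hc_left_vs_right_p")
                  %in% names(r1$table2)))
  ps <- unlist(r1$table2[grepl("_p$", names(r1$table2))])
  expect_true(all(is.na(ps) | (ps >= 0 & ps <= 1)))
  # Holm never decreases a p-value
  rh <- runFullAnalysis(coh$manifest, feats, holm = TRUE)
  expect_true(all(rh$table2$ptn_left_vs_right_p >=
                    r1$table2$ptn_left_vs_right_p - 1e-15))
  # a failing stage names itself
  expect_error(runFullAnalysis(coh$manifest, feats[1:5, ]),
               "subject_table")
})
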