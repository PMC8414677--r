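# The statistical battery: binomial laterality test, paired side
# comparisons, regression-based group comparisons, Kendall tau-b
# correlation screen, and the demographic / NVC cross-tabulation /
# no-NVC subgroup table builders. Two-sided tests throughout, alpha
# 0.05, no multiple-testing correction by default (a Holm option is
# available); the unadjusted default mirrors the marginal per-feature
# testing of the study design this package emulates.

#' Join manifest and per-mask features into a per-side subject table
#'
#' One row per subject and side, carrying group, affected flag and NVC
#' status next to the ten features; the unit of analysis for all
#' downstream comparisons.
#'
#' @param manifest a [CohortManifest].
#' @param features data.frame from [extractCohortFeatures()] (columns
#'   subject_id, side, features).
#' @return data.frame with columns subject_id, side, group,
#'   affected_side, affected (logical), nvc (yes/no for that side) and
#'   the ten feature columns.
#' @export
buildSubjectTable <- function(manifest, features) {
  d <- manifestData(manifest)
  need <- c("subject_id", "side", featureNames())
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("feature table is missing columns: ", paste(miss, collapse = ", "))
  meta <- rbind(
    data.frame(subject_id = d$subject_id, side = "left", group = d$group,
               affected_side = d$affected_side, nvc = d$nvc_left),
    data.frame(subject_id = d$subject_id, side = "right", group = d$group,
               affected_side = d$affected_side, nvc = d$nvc_right))
  tab <- merge(meta, features[need], by = c("subject_id", "side"))
  if (nrow(tab) != 2L * nrow(d))
    stop("features missing for some subject/side combinations (got ",
         nrow(tab), " rows, expected ", 2L * nrow(d), ")")
  tab$affected <- tab$side == tab$affected_side
  tab[order(tab$subject_id, tab$side), ]
}

#' Exact binomial test of affected-side laterality
#'
#' Two-sided exact binomial test of the right-side count against
#' p = 0.5, reporting the left/right proportions.
#'
#' @param nLeft,nRight counts of left- and right-affected patients.
#' @return a [ComparisonResult]; means hold the left/right proportions
#'   in percent.
#' @export
binomialLateralityTest <- function(nLeft, nRight) {
  stopifnot(nLeft >= 0, nRight >= 0)
  n <- nLeft + nRight
  if (n == 0) stop("both counts are zero")
  bt <- stats::binom.test(nRight, n, p = 0.5)
  .comparison("affected side left vs right", "exact binomial",
              nA = nLeft, nB = nRight,
              meanA = 100 * nLeft / n, sdA = NA_real_,
              meanB = 100 * nRight / n, sdB = NA_real_,
              statistic = nRight, p = bt$p.value)
}

# within-subject wide pairs for one feature; arms as (A, B) columns
.pairedArms <- function(subjectTable, feature, pairing, group) {
  tab <- subjectTable[subjectTable$group == group, ]
  if (pairing == "affected_unaffected") {
    a <- tab[tab$affected, c("subject_id", feature)]
    b <- tab[!tab$affected & tab$affected_side != "none",
             c("subject_id", feature)]
    labs <- c("affected", "unaffected")
  } else if (pairing == "left_right") {
    a <- tab[tab$side == "left", c("subject_id", feature)]
    b <- tab[tab$side == "right", c("subject_id", feature)]
    labs <- c("left", "right")
  } else stop("pairing must be 'affected_unaffected' or 'left_right'")
  m <- merge(a, b, by = "subject_id", suffixes = c("_a", "_b"))
  list(a = m[[paste0(feature, "_a")]], b = m[[paste0(feature, "_b")]],
       labs = labs)
}

#' Paired within-subject side comparison of one feature
#'
#' Two-sided paired t-test on within-subject differences between the
#' two sides of the requested stratum.
#'
#' @param subjectTable from [buildSubjectTable()].
#' @param feature one of [featureNames()].
#' @param pairing `"affected_unaffected"` (PTN only) or `"left_right"`.
#' @param group stratum, "PTN" or "HC".
#' @return a [ComparisonResult]. Strata with fewer than 3 complete
#'   pairs, or zero within-pair variance, are flagged (note set, p NA)
#'   rather than tested.
#' @export
pairedSideComparison <- function(subjectTable, feature,
                                 pairing = c("affected_unaffected",
                                             "left_right"),
                                 group = "PTN") {
  pairing <- match.arg(pairing)
  stopifnot(feature %in% featureNames())
  pa <- .pairedArms(subjectTable, feature, pairing, group)
  contrast <- paste0(group, " ", pa$labs[1], " vs ", pa$labs[2],
                     ": ", feature)
  n <- length(pa$a)
  mk <- function(stat = NA_real_, p = NA_real_, note = "")
    .comparison(contrast, "paired t-test", n, n,
                mean(pa$a), stats::sd(pa$a), mean(pa$b), stats::sd(pa$b),
                statistic = stat, p = p, paired = TRUE, note = note)
  if (n < 3) return(mk(note = sprintf("stratum too small (n=%d)", n)))
  if (anyNA(pa$a) || anyNA(pa$b))
    return(mk(note = "missing feature values"))
  diffs <- pa$a - pa$b
  if (stats::sd(diffs) == 0)
    return(mk(note = "zero within-pair variance"))
  tt <- stats::t.test(pa$a, pa$b, paired = TRUE)
  mk(unname(tt$statistic), tt$p.value)
}

#' Group comparison of one feature by linear regression on an arm
#' indicator
#'
#' Ordinary least squares of the feature on a 0/1 arm indicator; the
#' indicator's coefficient t-test is reported, which under equal
#' variances is numerically the pooled two-sample t-test. A Welch
#' t-test fallback is available with `welch = TRUE`.
#'
#' @param subjectTable from [buildSubjectTable()].
#' @param feature one of [featureNames()].
#' @param armA,armB logical vectors over the rows of `subjectTable`
#'   selecting the two (disjoint) arms.
#' @param labels character(2) arm labels for the contrast name.
#' @param welch use Welch's unequal-variance t-test instead of OLS.
#' @return a [ComparisonResult].
#' @export
groupComparison <- function(subjectTable, feature, armA, armB,
                            labels = c("A", "B"), welch = FALSE) {
  stopifnot(feature %in% featureNames(),
            length(armA) == nrow(subjectTable),
            length(armB) == nrow(subjectTable))
  if (any(armA & armB)) stop("arms must be disjoint")
  xa <- subjectTable[[feature]][armA]
  xb <- subjectTable[[feature]][armB]
  contrast <- paste0(labels[1], " vs ", labels[2], ": ", feature)
  if (length(xa) == 0 || length(xb) == 0) stop("empty arm")
  mk <- function(stat = NA_real_, p = NA_real_, test, note = "")
    .comparison(contrast, test, length(xa), length(xb),
                mean(xa), stats::sd(xa), mean(xb), stats::sd(xb),
                statistic = stat, p = p, note = note)
  if (length(xa) < 3 || length(xb) < 3)
    return(mk(test = "OLS group indicator",
              note = sprintf("arm too small (n=%d/%d)",
                             length(xa), length(xb))))
  if (welch) {
    tt <- stats::t.test(xa, xb)
    return(mk(unname(tt$statistic), tt$p.value, "Welch t-test"))
  }
  y <- c(xa, xb)
  g <- rep(c(0, 1), c(length(xa), length(xb)))
  if (stats::sd(y) == 0)
    return(mk(0, 1, "OLS group indicator", note = "constant outcome"))
  fit <- summary(stats::lm(y ~ g))$coefficients
  mk(fit["g", "t value"], fit["g", "Pr(>|t|)"], "OLS group indicator")
}

#' Kendall tau-b screen of flatness against the other nine features
#'
#' Tie-corrected Kendall rank correlation of flatness with each other
#' feature over all masks of one group, ordered by decreasing absolute
#' tau.
#'
#' @param subjectTable from [buildSubjectTable()].
#' @param group "PTN" or "HC".
#' @return data.frame with columns feature, tau, p, note, sorted by
#'   |tau| descending. Constant features are flagged (tau NA).
#' @export
kendallCorrelationScreen <- function(subjectTable, group = "PTN") {
  tab <- subjectTable[subjectTable$group == group, ]
  if (nrow(tab) < 5) stop("need >= 5 masks in group ", group)
  fl <- tab$flatness
  others <- setdiff(featureNames(), "flatness")
  res <- lapply(others, function(f) {
    x <- tab[[f]]
    if (anyNA(x) || stats::sd(x) == 0 || stats::sd(fl) == 0)
      return(data.frame(feature = f, tau = NA_real_, p = NA_real_,
                        note = "constant or missing feature"))
    ct <- suppressWarnings(stats::cor.test(fl, x, method = "kendall"))
    data.frame(feature = f, tau = unname(ct$estimate), p = ct$p.value,
               note = "")
  })
  res <- do.call(rbind, res)
  res[order(-abs(res$tau)), ]
}

#' Demographics table (Table-1 analogue)
#'
#' Counts and percentages of cases and masks per group, the sex
#' breakdown with a chi-square test (Pearson, continuity correction off
#' by default), a two-sample t-test on age, and the affected-side
#' laterality with its exact binomial p-value.
#'
#' @param manifest a [CohortManifest]; `age`/`sex` may be manifest
#'   columns or supplied explicitly.
#' @param ages,sexes optional per-subject vectors overriding manifest
#'   columns.
#' @param yates apply Yates continuity correction to the chi-square.
#' @param welch Welch t-test for age instead of pooled.
#' @return data.frame with columns row, ptn, ptn_pct, hc, hc_pct,
#'   total, p, test. Missing covariates flag their row instead of
#'   erroring.
#' @export
demographicsTable <- function(manifest, ages = NULL, sexes = NULL,
                              yates = FALSE, welch = FALSE) {
  d <- manifestData(manifest)
  if (is.null(ages) && "age" %in% names(d)) ages <- d$age
  if (is.null(sexes) && "sex" %in% names(d)) sexes <- d$sex
  ptn <- d$group == "PTN"; hc <- d$group == "HC"
  n <- nrow(d)
  row <- function(row, ptnN, hcN, denomPtn = n, denomHc = n,
                  p = NA_real_, test = "")
    data.frame(row = row, ptn = ptnN,
               ptn_pct = round(100 * ptnN / denomPtn, 2),
               hc = hcN, hc_pct = round(100 * hcN / denomHc, 2),
               total = ptnN + hcN, p = p, test = test)
  out <- list(row("case_number", sum(ptn), sum(hc)),
              row("mc_number", 2 * sum(ptn), 2 * sum(hc), 2 * n, 2 * n))
  if (!is.null(sexes) && !anyNA(sexes)) {
    tabsex <- table(factor(d$group, c("PTN", "HC")),
                    factor(sexes, c("male", "female")))
    # Pearson chi-square reported as-is; small synthetic cohorts would
    # otherwise warn about the asymptotic approximation on every run
    psex <- suppressWarnings(
      stats::chisq.test(tabsex, correct = yates))$p.value
    out <- c(out, list(
      row("male", tabsex["PTN", "male"], tabsex["HC", "male"],
          sum(ptn), sum(hc), p = psex, test = "chi-square"),
      row("female", tabsex["PTN", "female"], tabsex["HC", "female"],
          sum(ptn), sum(hc))))
  } else {
    out <- c(out, list(row("sex", NA, NA, test = "missing covariate")))
  }
  if (!is.null(ages) && !anyNA(ages)) {
    tt <- stats::t.test(ages[ptn], ages[hc], var.equal = !welch)
    age <- data.frame(row = "age_mean_sd",
                      ptn = round(mean(ages[ptn]), 2),
                      ptn_pct = round(stats::sd(ages[ptn]), 2),
                      hc = round(mean(ages[hc]), 2),
                      hc_pct = round(stats::sd(ages[hc]), 2),
                      total = NA, p = tt$p.value, test = "t-test")
    out <- c(out, list(age))
  } else {
    out <- c(out, list(row("age", NA, NA, test = "missing covariate")))
  }
  nL <- sum(d$affected_side == "left"); nR <- sum(d$affected_side == "right")
  if (nL + nR > 0) {
    lat <- binomialLateralityTest(nL, nR)
    out <- c(out, list(
      row("affected_left", nL, 0, sum(ptn), 1, p = lat@p,
          test = "exact binomial"),
      row("affected_right", nR, 0, sum(ptn), 1)))
  }
  do.call(rbind, out)
}

#' NVC cross-tabulation (Table-3 analogue)
#'
#' Counts and percentages of the four (affected-side NVC,
#' unaffected-side NVC) patterns among left- and right-affected
#' patients; percentages are relative to that side's patient count.
#'
#' @param manifest a [CohortManifest] (PTN rows are used).
#' @return data.frame with columns affected_side, nvc_affected,
#'   nvc_unaffected, n, pct.
#' @export
nvcCrosstab <- function(manifest) {
  d <- manifestData(manifest)
  d <- d[d$group == "PTN", ]
  pats <- data.frame(nvc_affected = c("yes", "no", "yes", "no"),
                     nvc_unaffected = c("no", "yes", "yes", "no"))
  out <- list()
  for (side in c("left", "right")) {
    ds <- d[d$affected_side == side, ]
    aff <- if (side == "left") ds$nvc_left else ds$nvc_right
    una <- if (side == "left") ds$nvc_right else ds$nvc_left
    nside <- nrow(ds)
    cnt <- mapply(function(a, u) sum(aff == a & una == u),
                  pats$nvc_affected, pats$nvc_unaffected)
    out[[side]] <- cbind(data.frame(affected_side = side), pats,
                         n = as.integer(cnt),
                         pct = if (nside > 0)
                           round(100 * cnt / nside, 1) else NA_real_)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Paired comparisons in the no-NVC subgroup (Table-4 analogue)
#'
#' Restricts to patients with NVC "no" on both sides and runs the
#' affected-vs-unaffected paired comparison of all ten features
#' separately for left- and right-affected patients.
#'
#' @param subjectTable from [buildSubjectTable()].
#' @return data.frame with one row per (affected_side, feature):
#'   per-arm n/mean/sd, statistic, p, note ("stratum too small" when a
#'   subgroup has fewer than 3 pairs).
#' @export
noNvcSubgroupComparison <- function(subjectTable) {
  noNvc <- subjectTable$group == "PTN" & subjectTable$nvc == "no"
  # subjects whose BOTH sides are NVC-free
  bySubj <- tapply(noNvc, subjectTable$subject_id, all)
  keep <- names(bySubj)[bySubj]
  tab <- subjectTable[subjectTable$subject_id %in% keep &
                        subjectTable$group == "PTN", ]
  out <- list()
  for (side in c("left", "right")) {
    sub <- tab[tab$affected_side == side, ]
    for (f in featureNames()) {
      cr <- pairedSideComparison(sub, f, "affected_unaffected", "PTN")
      rowdf <- as.data.frame(cr)
      rowdf$affected_side <- side
      out[[paste(side, f)]] <- rowdf[, c("affected_side", "contrast",
                                         "n_a", "mean_a", "sd_a",
                                         "n_b", "mean_b", "sd_b",
                                         "statistic", "p", "note")]
    }
  }
  res <- do.call(rbind, out)
  res$feature <- rep(featureNames(), 2)
  rownames(res) <- NULL
  res[, c("affected_side", "feature", "n_a", "mean_a", "sd_a", "n_b",
          "mean_b", "sd_b", "statistic", "p", "note")]
}

# Table-2 analogue: per feature, the four comparison blocks
.morphologyTable <- function(subjectTable, welch = FALSE, holm = FALSE) {
  blocks <- list()
  for (f in featureNames()) {
    hcAll <- subjectTable$group == "HC"
    ptnAff <- subjectTable$group == "PTN" & subjectTable$affected
    g <- groupComparison(subjectTable, f, hcAll, ptnAff,
                         labels = c("HC both sides", "PTN affected"),
                         welch = welch)
    pAU <- pairedSideComparison(subjectTable, f, "affected_unaffected", "PTN")
    pLRp <- pairedSideComparison(subjectTable, f, "left_right", "PTN")
    pLRh <- pairedSideComparison(subjectTable, f, "left_right", "HC")
    fmt <- function(cr, tag) {
      d <- data.frame(cr@mean[1], cr@sd[1], cr@mean[2], cr@sd[2], cr@p)
      names(d) <- paste0(tag, c("_mean_a", "_sd_a", "_mean_b", "_sd_b", "_p"))
      d
    }
    blocks[[f]] <- cbind(data.frame(feature = f),
                         fmt(g, "hc_vs_ptn_affected"),
                         fmt(pAU, "ptn_affected_vs_unaffected"),
                         fmt(pLRp, "ptn_left_vs_right"),
                         fmt(pLRh, "hc_left_vs_right"))
  }
  res <- do.call(rbind, blocks)
  rownames(res) <- NULL
  if (holm)
    for (cc in grep("_p$", names(res), value = TRUE))
      res[[cc]] <- stats::p.adjust(res[[cc]], "holm")
  res
}

# tiny polynomial string hash for run-log config fingerprints
.configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full stratified analysis (Tables 1-4 analogues)
#'
#' Builds the demographics table, the four-block morphology comparison
#' table, the NVC cross-tabulation, the no-NVC subgroup table and the
#' Kendall correlation screens, optionally writing `table1.csv` ...
#' `table4.csv`, `kendall_ptn.csv`, `kendall_hc.csv` and a `run.log`
#' (package version, seed, config hash) to `outDir`.
#'
#' @param manifest a [CohortManifest].
#' @param features data.frame from [extractCohortFeatures()].
#' @param outDir optional output directory.
#' @param holm apply Holm correction within each morphology-table
#'   block (off by default; the unadjusted default matches marginal
#'   per-feature testing).
#' @param welch use Welch tests for the group comparisons.
#' @param seed seed to record in the run log.
#' @return list with elements table1..table4, kendall_ptn, kendall_hc,
#'   subject_table and log (character).
#' @export
runFullAnalysis <- function(manifest, features, outDir = NULL,
                            holm = FALSE, welch = FALSE, seed = NA) {
  stages <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("analysis stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  tab <- stages("subject_table", buildSubjectTable(manifest, features))
  t1 <- stages("table1", demographicsTable(manifest))
  t2 <- stages("table2", .morphologyTable(tab, welch = welch, holm = holm))
  t3 <- stages("table3", nvcCrosstab(manifest))
  t4 <- stages("table4", noNvcSubgroupComparison(tab))
  kp <- stages("kendall_ptn", kendallCorrelationScreen(tab, "PTN"))
  kh <- if (any(tab$group == "HC"))
    stages("kendall_hc", kendallCorrelationScreen(tab, "HC")) else NULL
  cfg <- list(holm = holm, welch = welch, n = nSubjects(manifest))
  log <- c(paste0("MCmorph version: ",
                  as.character(utils::packageVersion("MCmorph"))),
           paste0("seed: ", seed),
           paste0("config hash: ", .configHash(cfg)),
           paste0("subjects: ", nSubjects(manifest)),
           paste0("holm: ", holm, "  welch: ", welch))
  res <- list(table1 = t1, table2 = t2, table3 = t3, table4 = t4,
              kendall_ptn = kp, kendall_hc = kh,
              subject_table = tab, log = log)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    for (nm in c("table1", "table2", "table3", "table4"))
      utils::write.csv(res[[nm]], file.path(outDir, paste0(nm, ".csv")),
                       row.names = FALSE)
    utils::write.csv(kp, file.path(outDir, "kendall_ptn.csv"),
                     row.names = FALSE)
    if (!is.null(kh))
      utils::write.csv(kh, file.path(outDir, "kendall_hc.csv"),
                       row.names = FALSE)
    writeLines(log, file.path(outDir, "run.log"))
  }
  res
}
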