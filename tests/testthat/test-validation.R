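## helpers to build spectra containing chosen theoretical ions exactly
spectrumFromIons <- function(mzs, gp, activation = "HCD", extraMz = numeric(),
                             extraInt = numeric()) {
  z <- 2L
  spectrum(c(mzs, extraMz), c(rep(100, length(mzs)), extraInt),
           activation = activation,
           precursorMz = (glycopeptideMass(gp) + z * ORACLE_PROTON) / z,
           precursorCharge = z)
}

test_that("naked-peptide check accepts Y0 and the oxidized-Met loss surrogate", {
  gp <- glycopeptide("AVFTTA", siteGlycans = list(`4` = "N1"))
  y0 <- peptideMass(gp) + ORACLE_PROTON
  hcd <- spectrumFromIons(y0, gp)
  expect_true(checkNakedPeptide(gp, hcd)$pass)

  gpM <- glycopeptide("AMFTTA", siteGlycans = list(`4` = "N1"),
                      oxMetPositions = 2L)
  lossMz <- peptideMass(gpM) - 63.9983 + ORACLE_PROTON
  hcdM <- spectrumFromIons(lossMz, gpM)
  expect_true(checkNakedPeptide(gpM, hcdM)$pass)

  none <- spectrumFromIons(450.123, gp)
  expect_false(checkNakedPeptide(gp, none)$pass)
})

test_that("backbone coverage applies the short/long regimes and the Pro rules", {
  gp <- glycopeptide("AVFTTA", siteGlycans = list(`4` = "N1"))
  th <- theoreticalFragments(gp, series = c("b", "y"), maxCharge = 1,
                             includeY0 = FALSE)
  full <- matchPeaks(spectrumFromIons(th$mz[th$series == "b"], gp), th)
  covFull <- checkBackboneCoverage(gp, full)
  expect_true(covFull$pass)
  expect_equal(covFull$coverage, 1.0)

  # C-terminal Pro: b(n-1) covers the final bond
  gpP <- glycopeptide("AVFTTP", siteGlycans = list(`4` = "N1"))
  thP <- theoreticalFragments(gpP, series = "b", maxCharge = 1,
                              includeY0 = FALSE)
  b5only <- matchPeaks(
    spectrumFromIons(thP$mz[thP$series == "b" & thP$index == 5], gpP), thP)
  covP <- checkBackboneCoverage(gpP, b5only)
  expect_equal(covP$coverage, 1 / 5)      # only the final bond
  expect_false(covP$pass)                 # short peptide still needs ~full b/y

  # long peptide: required bonds are those flanking Pro (N-terminal) and
  # Asp (C-terminal); a missing Pro bond fails regardless of overall coverage
  pep <- "AVKLEGWFKAVKLEGWFKAV"
  pep <- paste0(substr(pep, 1, 7), "P", substr(pep, 9, 20))
  gpL <- glycopeptide(pep)
  thL <- theoreticalFragments(gpL, series = c("b", "y"), maxCharge = 1,
                              includeY0 = FALSE)
  allButBond7 <- thL[!(thL$series == "b" & thL$index == 7) &
                       !(thL$series == "y" & thL$index == nchar(pep) - 7), ]
  mL <- matchPeaks(spectrumFromIons(allButBond7$mz, gpL), thL)
  covL <- checkBackboneCoverage(gpL, mL)
  expect_false(covL$pass)
  expect_true(7 %in% covL$requiredBonds)
  mAll <- matchPeaks(spectrumFromIons(thL$mz, gpL), thL)
  expect_true(checkBackboneCoverage(gpL, mAll)$pass)
})

test_that("c/z localization matches bracketing evidence and records contradictions", {
  gp <- glycopeptide("ATSA", siteGlycans = list(`2` = "N1"))
  th <- theoreticalFragments(gp, series = c("c", "z"), maxCharge = 1,
                             includeY0 = FALSE)
  # c2 and c3 both retain N1: the glycan is bracketed onto T2
  etd <- spectrumFromIons(th$mz[th$series == "c" & th$index %in% 2:3], gp,
                          activation = "EThcD")
  loc <- localizeGlycans(gp, etd)
  expect_identical(unname(loc$siteStatus[c("2", "3")]),
                   c("localized", "localized"))
  expect_identical(loc$assignment[["2"]], "N1")

  # only c1/z1 matched: no ion between T2 and S3, both unlocalized
  etd2 <- spectrumFromIons(th$mz[th$index == 1], gp, activation = "EThcD")
  loc2 <- localizeGlycans(gp, etd2)
  expect_identical(unname(loc2$siteStatus[c("2", "3")]),
                   c("unlocalized", "unlocalized"))

  # glycan-free c3 while both sites carry glycans: no arrangement fits
  gpBoth <- glycopeptide("ATSA", siteGlycans = list(`2` = "N1", `3` = "N1"))
  cz <- theoreticalFragments(glycopeptide("ATSA"), series = "c",
                             maxCharge = 1, includeY0 = FALSE)
  etd3 <- spectrumFromIons(cz$mz[cz$index == 3], gpBoth,
                           activation = "EThcD")
  loc3 <- localizeGlycans(gpBoth, etd3)
  expect_true(all(loc3$siteStatus == "contradicted"))
  expect_identical(loc3$nConsistent, 0L)

  # no ETD spectrum: everything unlocalized
  loc4 <- localizeGlycans(gp, NULL)
  expect_true(all(loc4$siteStatus == "unlocalized"))
})

test_that("localization agrees with a brute-force arrangement oracle", {
  # oracle: enumerate all glycan-to-site arrangements, keep those whose
  # implied c/z fragment m/z set contains every observed peak, and call a
  # site localized when the survivors agree
  oracleLocalize <- function(pep, glycans, trueSites, obsMz, tol = 0.01) {
    res <- strsplit(pep, "")[[1]]
    sites <- which(res %in% c("S", "T"))
    n <- length(res)
    arrangeAll <- function(gly, st) {
      if (!length(gly)) return(list(integer(0)))
      out <- list()
      subsets <- utils::combn(st, length(gly), simplify = FALSE)
      perm <- function(v) {
        if (length(v) <= 1) return(list(v))
        o <- list()
        for (i in seq_along(v))
          for (r in perm(v[-i])) o[[length(o) + 1]] <- c(v[i], r)
        unique(o)
      }
      for (s in subsets) for (p in perm(gly))
        out[[length(out) + 1]] <- stats::setNames(p, s)
      unique(out)
    }
    fragSet <- function(a) {
      gvec <- numeric(n)
      if (length(a)) gvec[as.integer(names(a))] <- ORACLE_GLY["N"] * a
      mz <- c()
      for (i in 1:(n - 1)) {
        mz <- c(mz, sum(ORACLE_AA[res[1:i]]) + ORACLE_NH3 + sum(gvec[1:i]) +
                  ORACLE_PROTON)
        mz <- c(mz, sum(ORACLE_AA[res[(n - i + 1):n]]) + 1.9918406 +
                  sum(gvec[(n - i + 1):n]) + ORACLE_PROTON)
      }
      mz
    }
    arrs <- arrangeAll(glycans, sites)
    ok <- vapply(arrs, function(a)
      all(vapply(obsMz, function(m) any(abs(fragSet(a) - m) < tol),
                 logical(1))), logical(1))
    if (!any(ok)) return(stats::setNames(rep("contradicted", length(sites)),
                                         sites))
    vapply(as.character(sites), function(s) {
      g <- vapply(arrs[ok], function(a)
        if (s %in% names(a)) a[[s]] else 0, numeric(1))
      if (length(unique(g)) == 1) "localized" else "unlocalized"
    }, character(1))
  }

  for (seed in 1:8) {
    pep <- randomPeptide(sample(5:8, 1), seed = 300 + seed)
    res <- strsplit(pep, "")[[1]]
    sites <- which(res %in% c("S", "T"))
    k <- min(length(sites), sample(1:2, 1))
    set.seed(400 + seed)
    trueSites <- sort(sites[sample.int(length(sites), k)])
    gp <- glycopeptide(pep, siteGlycans = stats::setNames(
      rep(list("N1"), k), trueSites))
    th <- theoreticalFragments(gp, series = c("c", "z"), maxCharge = 1,
                               includeY0 = FALSE)
    keep <- sort(sample(nrow(th), max(2, nrow(th) %/% 2)))
    obsMz <- th$mz[keep]
    etd <- spectrumFromIons(obsMz, gp, activation = "EThcD")
    got <- localizeGlycans(gp, etd, maxCharge = 1)$siteStatus
    want <- oracleLocalize(pep, rep(1, k), trueSites, obsMz)
    expect_identical(unname(got), unname(want),
                     info = paste(pep, seed))
  }
})

test_that("residual-mass matching recovers planted glycan masses", {
  gp <- glycopeptide("AVFTTA")
  mk <- function(neutral) spectrum(500, 100, precursorMz =
                                     (neutral + 2 * ORACLE_PROTON) / 2,
                                   precursorCharge = 2L)
  hits <- residualMatch(mk(1014.4757), gp)
  expect_identical(vapply(hits, formatComposition, character(1)), "N2")
  expect_length(residualMatch(mk(oraclePeptideMass("AVFTTA") - 5), gp), 0L)
  hits2 <- residualMatch(mk(oraclePeptideMass("AVFTTA") + 365.132), gp)
  expect_identical(vapply(hits2, formatComposition, character(1)), "N1H1")
})

test_that("identification transfer is scale-invariant and rejects noise", {
  gp <- glycopeptide("AVFTTA", siteGlycans = list(`4` = "N1"))
  th <- theoreticalFragments(gp, series = c("b", "y"), maxCharge = 1,
                             includeY0 = FALSE)
  strong <- spectrumFromIons(th$mz, gp)
  matches <- matchPeaks(strong, th)
  weak <- spectrum(peaks(strong)[, 1], peaks(strong)[, 2] * 0.1,
                   precursorMz = strong@precursorMz, precursorCharge = 2L)
  res <- transferIdentification(strong, matches, weak)
  expect_true(res$accept)
  expect_equal(res$similarity, 1.0, tolerance = 1e-9)

  set.seed(77)
  noise <- spectrum(sort(stats::runif(30, 150, 1200)),
                    stats::runif(30, 10, 100),
                    precursorMz = strong@precursorMz, precursorCharge = 2L)
  resN <- transferIdentification(strong, matches, noise)
  expect_false(resN$accept)
})

test_that("validate() composes the rules with the stated precedence", {
  gp <- glycopeptide("AVFTTA", siteGlycans = list(`4` = "N1", `5` = "N1"))
  th <- theoreticalFragments(gp, series = c("b", "y"), maxCharge = 1)
  allMz <- th$mz
  hcd <- spectrumFromIons(allMz, gp, extraMz = c(138.055, 144.07),
                          extraInt = c(100, 100))
  thCZ <- theoreticalFragments(gp, series = c("c", "z"), maxCharge = 1,
                               includeY0 = FALSE)
  etd <- spectrumFromIons(thCZ$mz, gp, activation = "EThcD")
  d <- validateGlycopeptide(gp, hcd, etd)
  expect_identical(d@status, "accept")
  expect_identical(unname(d@siteStatus[c("4", "5")]),
                   c("localized", "localized"))

  # missing Y0: reject regardless of coverage
  noY0 <- spectrumFromIons(th$mz[th$series != "Y"], gp)
  d2 <- validateGlycopeptide(gp, noY0, etd)
  expect_identical(d2@status, "reject")
  expect_false(d2@reasons$pass[d2@reasons$rule == "naked_peptide"])

  # N2 unlocalized over two sites with 138/144 < 1.2 and no 407:
  # decomposed into two N1 assignments
  gpU <- glycopeptide("AVFTTA", siteGlycans = list(`4` = "N2"))
  thU <- theoreticalFragments(gpU, series = c("b", "y"), maxCharge = 1)
  hcdU <- spectrumFromIons(thU$mz, gpU, extraMz = c(138.055, 144.07),
                           extraInt = c(100, 100))
  dU <- validateGlycopeptide(gpU, hcdU, etd = NULL)
  expect_identical(dU@status, "accept")
  expect_true(all(dU@siteStatus[c("4", "5")] == "unlocalized"))
  expect_identical(dU@siteGlycans[["4"]], "N1")
  expect_identical(dU@siteGlycans[["5"]], "N1")
  expect_true("core1_decomposition" %in% dU@reasons$rule)

  # with a 407 oxonium present the decomposition is withheld
  hcd407 <- spectrumFromIons(thU$mz, gpU,
                             extraMz = c(138.055, 144.07, 407.166),
                             extraInt = c(100, 100, 100))
  d407 <- validateGlycopeptide(gpU, hcd407, etd = NULL)
  expect_identical(d407@status, "accept")
  expect_false("core1_decomposition" %in% d407@reasons$rule)

  # determinism: identical inputs give identical decisions
  dAgain <- validateGlycopeptide(gp, hcd, etd)
  expect_identical(dAgain@status, d@status)
  expect_identical(dAgain@siteStatus, d@siteStatus)
  expect_identical(dAgain@reasons, d@reasons)
})

test_that("candidate scans are found by 204 extraction or trigger", {
  withOx <- spectrum(c(204.0867, 600), c(100, 1000), scanId = "ox",
                     precursorMz = 700, precursorCharge = 2L)
  plain <- spectrum(c(350, 600), c(80, 1000), scanId = "plain",
                    precursorMz = 700, precursorCharge = 2L)
  trig <- spectrum(c(126.055, 138.055, 292.103, 600), c(90, 90, 90, 1000),
                   scanId = "trig", precursorMz = 700, precursorCharge = 2L)
  found <- findCandidateScans(list(withOx, plain, trig))
  expect_setequal(found, c("ox", "trig"))
  expect_length(findCandidateScans(list()), 0L)
})

test_that("spectrum averaging merges peaks within tolerance and sums intensity", {
  a <- spectrum(c(200.000, 300.0), c(10, 20), precursorMz = 500,
                precursorCharge = 2L)
  b <- spectrum(c(200.001, 400.0), c(30, 5), precursorMz = 500,
                precursorCharge = 2L)
  avg <- averageSpectra(list(a, b), tolPpm = 10)
  pk <- peaks(avg)
  expect_equal(nrow(pk), 3L)
  expect_equal(unname(pk[1, "intensity"]), 40)
})
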