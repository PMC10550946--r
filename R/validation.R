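## The manual-validation rulebook as a deterministic engine.

#' Naked-peptide (Y0) check
#'
#' Passes when the HCD spectrum contains the precursor mass without a glycan
#' (Y0) at any charge 1..precursor charge. When the peptide carries an
#' oxidized Met, a peak at Y0 minus the oxidized-Met side-chain loss (CH4SO,
#' 63.9983 Da) also counts as representative of the naked peptide mass.
#'
#' @param gp a \linkS4class{Glycopeptide}.
#' @param hcd an HCD \linkS4class{Spectrum} with known precursor charge.
#' @param tolPpm mass tolerance in ppm.
#' @return list with \code{pass} and the matched evidence data.frame.
#' @export
checkNakedPeptide <- function(gp, hcd, tolPpm = 20) {
  stopifnot(is(gp, "Glycopeptide"), is(hcd, "Spectrum"))
  naked <- peptideMass(gp)
  neutrals <- c(Y0 = naked)
  if (length(gp@oxMetPositions))
    neutrals <- c(neutrals, Y0_metLoss = naked - .CONST$metOxLoss)
  z <- seq_len(max(1L, hcd@precursorCharge))
  theo <- do.call(rbind, lapply(names(neutrals), function(nm)
    data.frame(series = nm, index = 0L, charge = z,
               mz = .mzFromNeutral(neutrals[[nm]], z),
               glycanMass = 0, glycan = "", stringsAsFactors = FALSE)))
  m <- matchPeaks(hcd, theo, tolPpm)
  list(pass = nrow(m) > 0L, evidence = m)
}

#' Backbone b/y coverage check
#'
#' Short peptides (length <= \code{shortLength}) pass when the fraction of
#' backbone bonds covered by any matched b or y ion is at least
#' \code{minCoverage} ("nearly full coverage"). Longer peptides pass when all
#' expected-abundant bonds are covered: the bond N-terminal to every Pro and
#' the bond C-terminal to every Asp. A peptide with C-terminal Pro satisfies
#' its final bond by b(n-1) alone (which the b/y coverage rule already
#' grants).
#'
#' @param gp a \linkS4class{Glycopeptide}.
#' @param matches matched fragments from \code{\link{matchPeaks}} (b/y rows
#'   are used).
#' @param shortLength length threshold separating the two regimes.
#' @param minCoverage required covered-bond fraction for short peptides.
#' @return list with \code{pass}, \code{coverage} (fraction of bonds covered)
#'   and \code{requiredBonds} (for long peptides).
#' @export
checkBackboneCoverage <- function(gp, matches, shortLength = 12L,
                                  minCoverage = 0.8) {
  res <- .residues(gp)
  n <- length(res)
  nBonds <- n - 1L
  covered <- rep(FALSE, nBonds)
  if (!is.null(matches) && nrow(matches)) {
    b <- matches$index[matches$series == "b"]
    y <- matches$index[matches$series == "y"]
    covered[b[b >= 1L & b <= nBonds]] <- TRUE
    covered[n - y[y >= 1L & y <= nBonds]] <- TRUE
  }
  coverage <- mean(covered)
  if (n <= shortLength) {
    return(list(pass = coverage >= minCoverage, coverage = coverage,
                requiredBonds = integer()))
  }
  # expected abundant: bond N-terminal of Pro at p is bond p-1;
  # bond C-terminal of Asp at d is bond d
  proBonds <- which(res == "P") - 1L
  aspBonds <- which(res == "D")
  required <- sort(unique(c(proBonds[proBonds >= 1L],
                            aspBonds[aspBonds <= nBonds])))
  list(pass = all(covered[required]), coverage = coverage,
       requiredBonds = required)
}

## all distinct assignments of a glycan multiset onto candidate sites;
## returns list of named character vectors (site -> composition string)
.glycanArrangements <- function(glycanStrs, sites, maxArrangements = 20000L) {
  k <- length(glycanStrs)
  if (k == 0L) return(list(stats::setNames(character(0), character(0))))
  if (k > length(sites)) stop("more glycans than candidate sites")
  subsets <- utils::combn(sites, k, simplify = FALSE)
  perms <- unique(.permutations(glycanStrs))
  if (length(subsets) * length(perms) > maxArrangements)
    stop("too many glycan arrangements to enumerate")
  out <- list()
  for (sub in subsets)
    for (p in perms)
      out[[length(out) + 1L]] <- stats::setNames(p, sub)
  out
}

.permutations <- function(x) {
  n <- length(x)
  if (n <= 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    rest <- .permutations(x[-i])
    for (r in rest) out[[length(out) + 1L]] <- c(x[i], r)
  }
  out
}

## c/z fragment table (m/z plus retained-glycan mass) for one site->glycan
## arrangement, computed from prefix/suffix residue sums
.arrangementFragments <- function(prefix, suffix, siteMassVec, maxCharge) {
  n <- length(prefix)
  cumPre <- cumsum(siteMassVec)
  totalGly <- cumPre[n]
  i <- seq_len(n - 1L)
  cNeutral <- prefix[i] + .CONST$ammonia + cumPre[i]
  cGly <- cumPre[i]
  # z_j spans residues (n-j+1)..n
  zNeutral <- suffix[n - i + 1L] + .CONST$zdot + (totalGly - cumPre[n - i])
  zGly <- totalGly - cumPre[n - i]
  out <- list()
  for (z in seq_len(maxCharge)) {
    out[[length(out) + 1L]] <- data.frame(
      series = rep(c("c", "z"), each = n - 1L), index = c(i, i),
      charge = z, mz = .mzFromNeutral(c(cNeutral, zNeutral), z),
      glycanMass = c(cGly, zGly))
  }
  do.call(rbind, out)
}

#' Localize glycans from ETD/EThcD c/z evidence
#'
#' Every arrangement of the glycan multiset over the candidate Ser/Thr sites
#' is enumerated and tested for consistency with every matched c/z ion
#' (glycan-retaining c/z evidence outranks b/y and is the only evidence used
#' here). A site is localized when all arrangements consistent with the
#' evidence agree on that site's glycan; sites are contradicted when no
#' arrangement is consistent with the evidence.
#'
#' @param gp a \linkS4class{Glycopeptide}; its glycans form the multiset and
#'   all Ser/Thr positions are candidate sites.
#' @param etd an ETD or EThcD \linkS4class{Spectrum}, or NULL (all sites
#'   unlocalized).
#' @param tolPpm MS2 tolerance in ppm.
#' @param maxCharge maximum fragment charge considered.
#' @return list with \code{siteStatus} (named character: localized /
#'   unlocalized / contradicted), \code{assignment} (named list of
#'   composition strings for localized sites; "" = no glycan), and
#'   \code{nConsistent} (number of arrangements consistent with the
#'   evidence).
#' @export
localizeGlycans <- function(gp, etd, tolPpm = 20, maxCharge = NULL) {
  res <- .residues(gp)
  sites <- which(res %in% c("S", "T"))
  siteNames <- as.character(sites)
  glycanStrs <- vapply(gp@siteGlycans, formatComposition, character(1))
  glycanStrs <- glycanStrs[nzchar(glycanStrs)]
  unloc <- stats::setNames(rep("unlocalized", length(sites)), siteNames)
  if (is.null(etd) || !length(sites))
    return(list(siteStatus = unloc, assignment = list(), nConsistent = NA_integer_))
  if (is.null(maxCharge))
    maxCharge <- max(1L, etd@precursorCharge - 1L)

  arrangements <- .glycanArrangements(sort(glycanStrs), sites)
  rm <- .residueMasses(gp)
  n <- length(rm)
  prefix <- cumsum(rm)
  suffix <- rev(cumsum(rev(rm)))
  uniqStrs <- unique(glycanStrs)
  strMass <- stats::setNames(vapply(uniqStrs, compositionMass, numeric(1)),
                             uniqStrs)
  theoByArr <- lapply(arrangements, function(a) {
    siteMassVec <- numeric(n)
    if (length(a)) siteMassVec[as.integer(names(a))] <- strMass[a]
    .arrangementFragments(prefix, suffix, siteMassVec, maxCharge)
  })
  # also match fully glycan-free c/z variants so that evidence of a naked
  # fragment can contradict arrangements that require a glycan on it
  nakedTheo <- .arrangementFragments(prefix, suffix, numeric(n), maxCharge)
  theoAll <- rbind(do.call(rbind, theoByArr), nakedTheo)
  theoAll <- theoAll[!duplicated(paste(theoAll$series, theoAll$index,
                                       theoAll$charge,
                                       round(theoAll$glycanMass, 4))), ,
                     drop = FALSE]
  matched <- matchPeaks(etd, theoAll, tolPpm)

  key <- function(df) paste(df$series, df$index, df$charge,
                            round(df$glycanMass, 4))
  evidence <- unique(key(matched))
  consistent <- vapply(seq_along(arrangements), function(a) {
    all(evidence %in% key(theoByArr[[a]]))
  }, logical(1))

  if (!any(consistent)) {
    return(list(siteStatus = stats::setNames(rep("contradicted", length(sites)),
                                             siteNames),
                assignment = list(), nConsistent = 0L))
  }
  cons <- arrangements[consistent]
  status <- unloc
  assignment <- list()
  # with no c/z evidence at all, sites cannot be considered localized
  anyEvidence <- length(evidence) > 0L
  for (s in siteNames) {
    glyAt <- vapply(cons, function(a) if (s %in% names(a)) a[[s]] else "",
                    character(1))
    if (anyEvidence && length(unique(glyAt)) == 1L) {
      status[s] <- "localized"
      assignment[[s]] <- glyAt[1L]
    }
  }
  list(siteStatus = status, assignment = assignment,
       nConsistent = sum(consistent))
}

#' Find candidate glycopeptide scans in a run
#'
#' Returns HCD scans with a HexNAc oxonium peak (204.0867 m/z, +/- 0.1) above
#' the relative-intensity floor, unioned with scans passing the
#' oxonium-fingerprint ETD trigger.
#'
#' @param spectra list of \linkS4class{Spectrum}.
#' @param mzTol absolute m/z tolerance for the 204 extraction.
#' @param minRelIntensity relative-intensity floor.
#' @return character vector of scan ids.
#' @export
findCandidateScans <- function(spectra, mzTol = 0.1, minRelIntensity = 0.05) {
  hits <- vapply(spectra, function(sp) {
    if (sp@activation != "HCD") return(FALSE)
    pk <- sp@peaks
    if (!nrow(pk)) return(FALSE)
    base <- max(pk[, 2L])
    has204 <- any(abs(pk[, 1L] - .OXONIUM_HEXNAC) <= mzTol &
                    pk[, 2L] > minRelIntensity * base)
    has204 || shouldTriggerEtd(sp)$trigger
  }, logical(1))
  vapply(spectra[hits], scanId, character(1))
}

#' De novo residual-mass matching
#'
#' Subtracts the naked peptide mass from the precursor neutral mass and
#' matches the remaining mass to combinations of glycan masses.
#'
#' @param scan a \linkS4class{Spectrum} with known precursor charge.
#' @param gp the naked peptide as a \linkS4class{Glycopeptide} (its glycans,
#'   if any, are ignored).
#' @param tol absolute tolerance in Da.
#' @param bounds per-monosaccharide enumeration bounds.
#' @return list of candidate \linkS4class{GlycanComposition}; empty when the
#'   residual is negative beyond tolerance or nothing matches.
#' @export
residualMatch <- function(scan, gp, tol = 0.02,
                          bounds = c(N = 6, H = 6, A = 4, F = 3)) {
  stopifnot(is(scan, "Spectrum"), !is.na(scan@precursorMz))
  z <- scan@precursorCharge
  precursorNeutral <- (scan@precursorMz - .CONST$proton) * z
  naked <- peptideMass(gp)
  residual <- precursorNeutral - naked
  if (residual < -tol) return(list())
  enumerateCompositions(max(residual, 0), tol = tol, bounds = bounds)
}

#' Transfer an identification to a weaker spectrum by spectral matching
#'
#' After a strong spectrum has been fully validated, weaker spectra sharing
#' the same naked peptide with a different glycan are accepted when the
#' normalized dot product (cosine) over the strong spectrum's matched
#' backbone-fragment m/z channels reaches \code{minSimilarity}.
#'
#' @param strongSpec the validated strong \linkS4class{Spectrum}.
#' @param strongMatches matched backbone fragments (b/y) of the strong
#'   spectrum, from \code{\link{matchPeaks}}.
#' @param weakSpec the weak \linkS4class{Spectrum}.
#' @param minSimilarity acceptance threshold on the cosine similarity.
#' @param tolPpm channel tolerance in ppm.
#' @return list with \code{accept} and \code{similarity}.
#' @export
transferIdentification <- function(strongSpec, strongMatches, weakSpec,
                                   minSimilarity = 0.7, tolPpm = 20) {
  chan <- strongMatches[strongMatches$series %in% c("b", "y"), , drop = FALSE]
  if (!nrow(chan)) return(list(accept = FALSE, similarity = NA_real_))
  mzs <- chan$observedMz
  a <- chan$observedIntensity
  pk <- weakSpec@peaks
  b <- vapply(mzs, function(m) {
    sel <- abs(pk[, 1L] - m) / m * 1e6 <= tolPpm
    if (any(sel)) max(pk[sel, 2L]) else 0
  }, numeric(1))
  sim <- if (sum(b) == 0) 0 else sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  list(accept = sim >= minSimilarity, similarity = sim)
}

#' Validate a glycopeptide identification
#'
#' Combines the rulebook: the naked-peptide (Y0) check and the backbone b/y
#' coverage check are both necessary for acceptance; c/z localization sets
#' per-site status only. When localization leaves two or more glycan-bearing
#' sites unresolved and the HCD spectrum shows a 138/144 ratio under 1.2 with
#' no 407 m/z oxonium, the total composition is decomposed into equal core-1
#' (or smaller) parts assigned to the unresolved sites.
#'
#' @param gp a \linkS4class{Glycopeptide}.
#' @param hcd the HCD \linkS4class{Spectrum}.
#' @param etd optional ETD/EThcD \linkS4class{Spectrum}.
#' @param tolPpm MS2 tolerance in ppm.
#' @param shortLength,minCoverage see \code{\link{checkBackboneCoverage}}.
#' @return A \linkS4class{ValidationDecision}.
#' @export
validateGlycopeptide <- function(gp, hcd, etd = NULL, tolPpm = 20,
                                 shortLength = 12L, minCoverage = 0.8) {
  naked <- checkNakedPeptide(gp, hcd, tolPpm)
  theoBY <- theoreticalFragments(gp, series = c("b", "y"),
                                 maxCharge = max(1L, min(2L, hcd@precursorCharge - 1L)),
                                 includeY0 = FALSE)
  matches <- matchPeaks(hcd, theoBY, tolPpm)
  cov <- checkBackboneCoverage(gp, matches, shortLength, minCoverage)
  loc <- localizeGlycans(gp, etd, tolPpm)

  reasons <- data.frame(
    rule = c("naked_peptide", "backbone_coverage"),
    pass = c(naked$pass, cov$pass),
    detail = c(sprintf("%d Y0-related peaks", nrow(naked$evidence)),
               sprintf("coverage %.2f", cov$coverage)),
    stringsAsFactors = FALSE)

  status <- if (naked$pass && cov$pass) "accept" else "reject"

  siteGlycans <- loc$assignment
  glycanStrs <- vapply(gp@siteGlycans, formatComposition, character(1))
  totalComp <- Reduce(`+`, gp@siteGlycans, glycanComposition())
  unresolved <- names(loc$siteStatus)[loc$siteStatus == "unlocalized"]
  if (status == "accept" && length(unresolved) >= 2L &&
      sum(nzchar(glycanStrs)) >= 1L && compositionSize(totalComp) > 0L &&
      !any(loc$siteStatus == "localized")) {
    dec <- decomposeMultisite(totalComp, length(unresolved),
                              has407(hcd), fingerprintRatio(hcd))
    if (dec$split) {
      for (i in seq_along(unresolved))
        siteGlycans[[unresolved[i]]] <- formatComposition(dec$parts[[i]])
      reasons <- rbind(reasons, data.frame(
        rule = "core1_decomposition", pass = TRUE,
        detail = sprintf("%s split over %d sites",
                         formatComposition(totalComp), length(unresolved)),
        stringsAsFactors = FALSE))
    }
  }

  new("ValidationDecision", status = status, reasons = reasons,
      siteStatus = loc$siteStatus, siteGlycans = siteGlycans)
}

setMethod("show", "ValidationDecision", function(object) {
  cat("ValidationDecision:", object@status, "\n")
  for (i in seq_len(nrow(object@reasons)))
    cat(sprintf("  %-20s %s (%s)\n", object@reasons$rule[i],
                ifelse(object@reasons$pass[i], "pass", "FAIL"),
                object@reasons$detail[i]))
  if (length(object@siteStatus)) {
    cat("  sites:",
        paste(sprintf("%s=%s", names(object@siteStatus), object@siteStatus),
              collapse = ", "), "\n")
  }
})

#' Average multiple MS2 scans into a merged spectrum
#'
#' Intensity-summed peak merging within a ppm window, used to obtain a
#' stronger spectrum before validation.
#'
#' @param spectra list of \linkS4class{Spectrum} sharing a precursor.
#' @param tolPpm merge window in ppm.
#' @return a merged \linkS4class{Spectrum}.
#' @export
averageSpectra <- function(spectra, tolPpm = 10) {
  stopifnot(length(spectra) >= 1L)
  allPk <- do.call(rbind, lapply(spectra, peaks))
  allPk <- allPk[order(allPk[, 1L]), , drop = FALSE]
  mz <- allPk[, 1L]
  grp <- cumsum(c(1L, diff(mz) / mz[-length(mz)] * 1e6 > tolPpm))
  mzM <- tapply(mz * allPk[, 2L], grp, sum) / tapply(allPk[, 2L], grp, sum)
  intM <- tapply(allPk[, 2L], grp, sum)
  tmpl <- spectra[[1L]]
  spectrum(as.numeric(mzM), as.numeric(intM),
           scanId = paste0(tmpl@scanId, "_avg"), activation = tmpl@activation,
           precursorMz = tmpl@precursorMz,
           precursorCharge = tmpl@precursorCharge,
           retentionTime = tmpl@retentionTime)
}
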