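## Spectrum/glycopeptide constructors, theoretical fragment generation, peak
## matching, and the oxonium-fingerprint product-dependent ETD trigger.

#' Create a glycopeptide
#'
#' @param sequence single-letter amino-acid string.
#' @param siteGlycans named list of \linkS4class{GlycanComposition} (or
#'   composition strings); names are 1-based positions within the peptide and
#'   must point at Ser or Thr.
#' @param oxMetPositions integer positions of oxidized Met residues.
#' @param proteinId parent protein identifier.
#' @param proteinOffset 1-based start position in the parent protein.
#' @return A \linkS4class{Glycopeptide}. Carbamidomethyl Cys is fixed.
#' @export
glycopeptide <- function(sequence, siteGlycans = list(),
                         oxMetPositions = integer(),
                         proteinId = NA_character_, proteinOffset = 1L) {
  siteGlycans <- lapply(siteGlycans, function(g)
    if (is.character(g)) parseComposition(g) else g)
  new("Glycopeptide",
      sequence = sequence, siteGlycans = siteGlycans,
      oxMetPositions = as.integer(oxMetPositions),
      proteinId = proteinId, proteinOffset = as.integer(proteinOffset))
}

#' Create a centroided spectrum
#'
#' @param mz,intensity peak vectors (sorted internally by m/z).
#' @param scanId scan identifier.
#' @param activation "HCD", "ETD" or "EThcD".
#' @param precursorMz precursor m/z.
#' @param precursorCharge precursor charge state.
#' @param retentionTime retention time in minutes.
#' @return A \linkS4class{Spectrum}.
#' @export
spectrum <- function(mz, intensity, scanId = "scan1", activation = "HCD",
                     precursorMz = NA_real_, precursorCharge = 2L,
                     retentionTime = 0) {
  o <- order(mz)
  new("Spectrum", scanId = scanId, activation = activation,
      precursorMz = precursorMz, precursorCharge = as.integer(precursorCharge),
      retentionTime = retentionTime,
      peaks = cbind(mz = mz[o], intensity = intensity[o]))
}

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum %s [%s] precursor %.4f m/z z=%d, %d peaks, rt %.2f min\n",
              object@scanId, object@activation, object@precursorMz,
              object@precursorCharge, nrow(object@peaks), object@retentionTime))
})

setMethod("show", "Glycopeptide", function(object) {
  sg <- object@siteGlycans
  gl <- if (length(sg))
    paste(sprintf("%s@%s", vapply(sg, formatComposition, character(1)),
                  names(sg)), collapse = ", ") else "none"
  cat(sprintf("Glycopeptide %s (glycans: %s), naked %.4f Da\n",
              object@sequence, gl, peptideMass(object)))
})

#' @rdname spectrum
#' @param object a \linkS4class{Spectrum}.
#' @export
peaks <- function(object) object@peaks

#' @rdname spectrum
#' @export
scanId <- function(object) object@scanId

.residues <- function(gp) strsplit(gp@sequence, "")[[1]]

## per-residue modified masses (carbamidomethyl Cys fixed, oxidized Met)
.residueMasses <- function(gp) {
  res <- .residues(gp)
  m <- .AA_MASS[res]
  m[res == "C"] <- m[res == "C"] + .CONST$cam
  if (length(gp@oxMetPositions))
    m[gp@oxMetPositions] <- m[gp@oxMetPositions] + .CONST$ox
  m
}

#' Naked (glycan-free) neutral monoisotopic peptide mass
#'
#' Residue masses plus water plus fixed/variable modification deltas,
#' excluding all glycans.
#'
#' @param gp a \linkS4class{Glycopeptide}.
#' @return neutral mass in Da.
#' @export
peptideMass <- function(gp) sum(.residueMasses(gp)) + .CONST$water

#' Intact neutral glycopeptide mass (naked mass plus all glycan masses)
#' @param gp a \linkS4class{Glycopeptide}.
#' @export
glycopeptideMass <- function(gp) {
  peptideMass(gp) + sum(vapply(gp@siteGlycans, compositionMass, numeric(1)))
}

.mzFromNeutral <- function(neutral, z) (neutral + z * .CONST$proton) / z

#' Theoretical fragment ions for a glycopeptide
#'
#' b/y ions are generated glycan-free by default (HCD convention; glycans are
#' typically lost) and optionally glycan-retaining; c/z ions are generated
#' glycan-retaining, each fragment keeping the glycans of the sites it spans.
#' z ions are modeled as z-dot (radical) species. Y0, the intact peptide
#' stripped of all glycans, is emitted at each charge 1..precursor charge.
#'
#' @param gp a \linkS4class{Glycopeptide}.
#' @param series character subset of c("b", "y", "c", "z").
#' @param maxCharge maximum fragment charge (>= 1).
#' @param y0Charges charges at which Y0 is generated (default 1..maxCharge).
#' @param glycanRetainingBY also emit glycan-retaining b/y ions.
#' @param includeY0 emit Y0 ions.
#' @return data.frame with columns series, index, charge, mz, glycanMass,
#'   glycan (canonical composition string retained on the fragment).
#' @export
theoreticalFragments <- function(gp, series = c("b", "y", "c", "z"),
                                 maxCharge = 1L, y0Charges = NULL,
                                 glycanRetainingBY = FALSE,
                                 includeY0 = TRUE) {
  stopifnot(is(gp, "Glycopeptide"), maxCharge >= 1L)
  res <- .residueMasses(gp)
  n <- length(res)
  if (n < 1L) stop("empty sequence")
  prefix <- cumsum(res)                       # residues 1..i
  suffix <- rev(cumsum(rev(res)))             # residues i..n
  sitePos <- as.integer(names(gp@siteGlycans))
  siteMass <- vapply(gp@siteGlycans, compositionMass, numeric(1))
  siteStr <- vapply(gp@siteGlycans, formatComposition, character(1))

  glycanOnPrefix <- function(i) {
    keep <- which(sitePos <= i)
    list(mass = sum(siteMass[keep]), str = .sumCompositionString(siteStr[keep]))
  }
  glycanOnSuffix <- function(firstRes) {
    keep <- which(sitePos >= firstRes)
    list(mass = sum(siteMass[keep]), str = .sumCompositionString(siteStr[keep]))
  }

  rows <- list()
  add <- function(ser, idx, z, neutral, gmass, gstr) {
    rows[[length(rows) + 1L]] <<- data.frame(
      series = ser, index = idx, charge = z,
      mz = .mzFromNeutral(neutral, z), glycanMass = gmass, glycan = gstr,
      stringsAsFactors = FALSE)
  }

  for (z in seq_len(maxCharge)) {
    for (i in seq_len(n - 1L)) {
      bN <- prefix[i]                    # b neutral = sum residues
      yN <- suffix[n - i + 1L] + .CONST$water
      gp_ <- glycanOnPrefix(i)
      gs_ <- glycanOnSuffix(n - i + 1L)
      if ("b" %in% series) {
        add("b", i, z, bN, 0, "")
        if (glycanRetainingBY && gp_$mass > 0) add("b", i, z, bN + gp_$mass, gp_$mass, gp_$str)
      }
      if ("y" %in% series) {
        add("y", i, z, yN, 0, "")
        if (glycanRetainingBY && gs_$mass > 0) add("y", i, z, yN + gs_$mass, gs_$mass, gs_$str)
      }
      if ("c" %in% series)
        add("c", i, z, bN + .CONST$ammonia + gp_$mass, gp_$mass, gp_$str)
      if ("z" %in% series)
        add("z", i, z, suffix[n - i + 1L] + .CONST$zdot + gs_$mass, gs_$mass, gs_$str)
    }
  }
  if (includeY0) {
    if (is.null(y0Charges)) y0Charges <- seq_len(maxCharge)
    naked <- peptideMass(gp)
    for (z in y0Charges) add("Y", 0L, z, naked, 0, "")
  }
  do.call(rbind, rows)
}

## canonical string for a sum of composition strings
.sumCompositionString <- function(strs) {
  if (!length(strs)) return("")
  total <- glycanComposition()
  for (s in strs) total <- total + parseComposition(s)
  formatComposition(total)
}

#' Match observed peaks against theoretical ions
#'
#' Greedy nearest-m/z assignment: each theoretical ion is matched to its
#' nearest observed peak within \code{tolPpm}. When several theoretical ions
#' claim the same observed peak, all matches are reported and flagged
#' ambiguous (the "?" semantics of manual annotation).
#'
#' @param spec a \linkS4class{Spectrum}.
#' @param theoretical data.frame from \code{\link{theoreticalFragments}}.
#' @param tolPpm mass tolerance in ppm (MS2 default 20).
#' @return the theoretical rows that matched, with added columns observedMz,
#'   observedIntensity, errorPpm, ambiguous.
#' @export
matchPeaks <- function(spec, theoretical, tolPpm = 20) {
  stopifnot(is(spec, "Spectrum"), tolPpm > 0)
  pk <- spec@peaks
  if (!nrow(pk) || is.null(theoretical) || !nrow(theoretical))
    return(cbind(theoretical[0, , drop = FALSE], observedMz = numeric(),
                 observedIntensity = numeric(), errorPpm = numeric(),
                 ambiguous = logical()))
  idx <- vapply(theoretical$mz, function(m) {
    j <- which.min(abs(pk[, 1L] - m))
    err <- (pk[j, 1L] - m) / m * 1e6
    if (abs(err) <= tolPpm) j else NA_integer_
  }, integer(1))
  hit <- !is.na(idx)
  out <- theoretical[hit, , drop = FALSE]
  j <- idx[hit]
  out$observedMz <- pk[j, 1L]
  out$observedIntensity <- pk[j, 2L]
  out$errorPpm <- (pk[j, 1L] - out$mz) / out$mz * 1e6
  out$ambiguous <- j %in% j[duplicated(j)]
  rownames(out) <- NULL
  out
}

#' Oxonium-fingerprint product-dependent ETD trigger
#'
#' An ETD scan is triggered on an HCD spectrum when (1) the precursor m/z is
#' within [300, 1500], (2) the precursor charge is 2..6, and (3) at least 3 of
#' the 8 HexNAc/NeuAc fingerprint ions (126.055, 138.055, 144.07, 168.065,
#' 186.076, 204.086, 274.092, 292.103 m/z) have a peak within +/- 0.1 m/z at
#' greater than 5% relative intensity (relative to the base peak).
#'
#' @param spec an HCD \linkS4class{Spectrum}.
#' @param minIons minimum number of distinct fingerprint ions (default 3).
#' @param mzTol absolute m/z tolerance (default 0.1).
#' @param minRelIntensity relative-intensity floor (default 0.05).
#' @param precursorRange allowed precursor m/z window.
#' @param chargeRange allowed precursor charge states.
#' @return list with elements \code{trigger} (logical) and \code{ionsFound}
#'   (the fingerprint m/z values satisfied).
#' @export
shouldTriggerEtd <- function(spec, minIons = 3L, mzTol = 0.1,
                             minRelIntensity = 0.05,
                             precursorRange = c(300, 1500),
                             chargeRange = 2:6) {
  stopifnot(is(spec, "Spectrum"))
  pk <- spec@peaks
  if (!nrow(pk)) return(list(trigger = FALSE, ionsFound = numeric()))
  base <- max(pk[, 2L])
  found <- .FINGERPRINT_MZ[vapply(.FINGERPRINT_MZ, function(f) {
    sel <- abs(pk[, 1L] - f) <= mzTol
    any(sel & pk[, 2L] > minRelIntensity * base)
  }, logical(1))]
  ok <- length(found) >= minIons &&
    !is.na(spec@precursorMz) &&
    spec@precursorMz >= precursorRange[1L] &&
    spec@precursorMz <= precursorRange[2L] &&
    spec@precursorCharge %in% chargeRange
  list(trigger = ok, ionsFound = found)
}

#' 138/144 oxonium intensity ratio
#'
#' Ratio of summed intensities within +/- 0.1 m/z of 138.055 and 144.07. A
#' ratio strictly under 1.2 indicates core 1 structures. Returns +Inf when the
#' 144 channel is empty but 138 is present, and NaN when both are empty.
#'
#' @param spec an HCD \linkS4class{Spectrum}.
#' @param mzTol absolute m/z tolerance (default 0.1).
#' @return numeric ratio.
#' @export
fingerprintRatio <- function(spec, mzTol = 0.1) {
  stopifnot(is(spec, "Spectrum"))
  pk <- spec@peaks
  i138 <- sum(pk[abs(pk[, 1L] - 138.055) <= mzTol, 2L])
  i144 <- sum(pk[abs(pk[, 1L] - 144.07) <= mzTol, 2L])
  if (i144 == 0 && i138 == 0) return(NaN)
  if (i144 == 0) return(Inf)
  i138 / i144
}

#' Is a di-HexNAc oxonium ion (407 m/z) present?
#'
#' Its presence indicates two HexNAc residues within a single glycan
#' structure and blocks the core-1 multi-site decomposition rule.
#'
#' @param spec an HCD \linkS4class{Spectrum}.
#' @param mzTol absolute m/z tolerance (default 0.1).
#' @param minRelIntensity relative-intensity floor (default 0.05).
#' @export
has407 <- function(spec, mzTol = 0.1, minRelIntensity = 0.05) {
  pk <- spec@peaks
  if (!nrow(pk)) return(FALSE)
  base <- max(pk[, 2L])
  any(abs(pk[, 1L] - .OXONIUM_DIHEXNAC) <= mzTol &
        pk[, 2L] > minRelIntensity * base)
}

## ---- MGF I/O ---------------------------------------------------------------

#' Read spectra from an MGF peak list
#'
#' Parses BEGIN IONS/END IONS blocks with TITLE, PEPMASS, CHARGE and
#' RTINSECONDS headers. The activation type is recovered from an
#' \code{activation=} token in the TITLE when present (HCD otherwise).
#'
#' @param path MGF file path.
#' @return list of \linkS4class{Spectrum}.
#' @export
readMgf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  stopifnot(length(starts) == length(ends))
  mapply(function(s, e) {
    block <- lines[(s + 1L):(e - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*", "", block[hdr])
    vals <- sub("^[^=]*=", "", block[hdr])
    names(vals) <- keys
    pkLines <- block[!hdr & nzchar(trimws(block))]
    pk <- if (length(pkLines)) {
      m <- do.call(rbind, lapply(strsplit(trimws(pkLines), "[ \t]+"), as.numeric))
      m
    } else matrix(numeric(), ncol = 2L)
    title <- if ("TITLE" %in% keys) vals[["TITLE"]] else "scan"
    act <- regmatches(title, regexpr("activation=[A-Za-z]+", title))
    act <- if (length(act)) sub("activation=", "", act) else "HCD"
    id <- regmatches(title, regexpr("scan=[^ ]+", title))
    id <- if (length(id)) sub("scan=", "", id) else title
    pep <- if ("PEPMASS" %in% keys)
      as.numeric(strsplit(vals[["PEPMASS"]], "[ \t]+")[[1]][1]) else NA_real_
    z <- if ("CHARGE" %in% keys)
      as.integer(sub("\\+$", "", vals[["CHARGE"]])) else 2L
    rt <- if ("RTINSECONDS" %in% keys)
      as.numeric(vals[["RTINSECONDS"]]) / 60 else 0
    spectrum(pk[, 1L], pk[, 2L], scanId = id, activation = act,
             precursorMz = pep, precursorCharge = z, retentionTime = rt)
  }, starts, ends, SIMPLIFY = FALSE)
}

#' Write spectra to an MGF peak list
#'
#' @param spectra list of \linkS4class{Spectrum}.
#' @param path output file path.
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      sprintf("TITLE=scan=%s activation=%s", sp@scanId, sp@activation),
      sprintf("PEPMASS=%.6f", sp@precursorMz),
      sprintf("CHARGE=%d+", sp@precursorCharge),
      sprintf("RTINSECONDS=%.3f", sp@retentionTime * 60),
      apply(sp@peaks, 1L, function(r) sprintf("%.6f %.4f", r[1L], r[2L])),
      "END IONS"), con)
  }
  invisible(path)
}
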