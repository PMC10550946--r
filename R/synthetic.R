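## Seeded generators producing every input the pipeline consumes, with
## planted ground truth for recovery tests. Every generator is a pure
## function of (seed, parameters).

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic mucin glycoprotein with planted glycosites
#'
#' The mucin region is Ser/Thr/Pro-rich; each Ser/Thr inside it is
#' glycosylated with probability \code{siteDensity}, drawing the glycan from
#' \code{glycanDistribution}. Reproducible from the seed.
#'
#' @param seed RNG seed.
#' @param length protein length in residues.
#' @param mucinRegion c(first, last) residue range of the mucin domain.
#' @param siteDensity probability in (0, 1] that a mucin-region Ser/Thr is
#'   glycosylated.
#' @param glycanDistribution named probability vector over composition
#'   strings.
#' @param id protein identifier.
#' @return list of class \code{syntheticGlycoprotein} with elements id,
#'   sequence, siteGlycans (named list, position -> GlycanComposition),
#'   mucinRegion and seed.
#' @export
makeGlycoprotein <- function(seed, length = 300L,
                             mucinRegion = c(ceiling(length * 0.3),
                                             floor(length * 0.8)),
                             siteDensity = 0.6,
                             glycanDistribution = c(N1 = 0.30, N1H1 = 0.30,
                                                    N1H1A1 = 0.20,
                                                    N1A1 = 0.10, N2H2 = 0.10),
                             id = paste0("synthMucin", seed)) {
  stopifnot(siteDensity > 0, siteDensity <= 1,
            abs(sum(glycanDistribution) - 1) < 1e-9)
  .withSeed(seed, {
    res <- sample(.AMINO_ACIDS, length, replace = TRUE)
    mucinLetters <- c(T = 0.25, S = 0.25, P = 0.20, A = 0.15, G = 0.10,
                      V = 0.05)
    span <- mucinRegion[1L]:mucinRegion[2L]
    res[span] <- sample(names(mucinLetters), length(span), replace = TRUE,
                        prob = mucinLetters)
    stPos <- span[res[span] %in% c("S", "T")]
    glycosylated <- stPos[stats::runif(length(stPos)) < siteDensity]
    glycans <- sample(names(glycanDistribution), length(glycosylated),
                      replace = TRUE, prob = glycanDistribution)
    siteGlycans <- stats::setNames(lapply(glycans, parseComposition),
                                   as.character(glycosylated))
    structure(list(id = id, sequence = paste(res, collapse = ""),
                   siteGlycans = siteGlycans, mucinRegion = mucinRegion,
                   seed = seed),
              class = "syntheticGlycoprotein")
  })
}

#' @export
print.syntheticGlycoprotein <- function(x, ...) {
  cat(sprintf("syntheticGlycoprotein %s: %d residues, mucin region %d..%d, %d glycosites\n",
              x$id, nchar(x$sequence), x$mucinRegion[1L], x$mucinRegion[2L],
              length(x$siteGlycans)))
  invisible(x)
}

#' Fraction of glycosites with a glycosylated immediate neighbor
#'
#' Adjacent glycosylated Ser/Thr pairs are the substrate feature that
#' separates SmE (tolerates a glycosylated P1) from ImpA (does not cleave
#' between two glycosylated residues).
#'
#' @param glycoprotein a \code{syntheticGlycoprotein}.
#' @export
adjacentGlycositeFraction <- function(glycoprotein) {
  pos <- sort(as.integer(names(glycoprotein$siteGlycans)))
  if (!length(pos)) return(0)
  mean((pos - 1L) %in% pos | (pos + 1L) %in% pos)
}

#' Strip sialic acids from all glycans (simulated sialidase co-treatment)
#'
#' @param glycoprotein a \code{syntheticGlycoprotein}.
#' @export
stripSialic <- function(glycoprotein) {
  glycoprotein$siteGlycans <- lapply(glycoprotein$siteGlycans, function(g) {
    cts <- g@counts
    cts["A"] <- 0L
    new("GlycanComposition", counts = cts)
  })
  glycoprotein
}

## ---- enzyme rules ----------------------------------------------------------

#' O-glycoprotease cleavage rules
#'
#' An enzyme rule decides, for each candidate scissile bond, whether cleavage
#' occurs; the cleavage position is the 1-based index of the P1' residue.
#' Presets encode the reported specificities: SmE cleaves N-terminally to any
#' glycosylated Ser/Thr and tolerates a glycosylated P1; ImpA additionally
#' requires an unglycosylated P1 (it does not cleave between two glycosylated
#' residues); OgpA is blocked when the P1' glycan contains NeuAc; StcE
#' requires the T/S*-X-T/S motif (glycosylated P1 with Ser/Thr at P2'), with
#' the scissile bond placed C-terminal to the glycosylated residue (before X)
#' by default.
#'
#' @param name enzyme name.
#' @param sitePredicate function(residues, glycosylated, glycans, p) ->
#'   logical deciding cleavage immediately N-terminal to residue p.
#' @return list of class \code{enzymeRule}.
#' @export
enzymeRule <- function(name, sitePredicate) {
  structure(list(name = name, sitePredicate = sitePredicate),
            class = "enzymeRule")
}

#' @rdname enzymeRule
#' @export
smeRule <- function() {
  enzymeRule("SmE", function(residues, glycosylated, glycans, p) {
    residues[p] %in% c("S", "T") && glycosylated[p]
  })
}

#' @rdname enzymeRule
#' @export
impaRule <- function() {
  enzymeRule("ImpA", function(residues, glycosylated, glycans, p) {
    residues[p] %in% c("S", "T") && glycosylated[p] && !glycosylated[p - 1L]
  })
}

#' @rdname enzymeRule
#' @export
ogpaRule <- function() {
  enzymeRule("OgpA", function(residues, glycosylated, glycans, p) {
    residues[p] %in% c("S", "T") && glycosylated[p] &&
      glycans[[as.character(p)]]@counts["A"] == 0L
  })
}

#' @rdname enzymeRule
#' @param scissile for StcE, where the scissile bond sits within the
#'   T/S*-X-T/S motif: "beforeX" (default, C-terminal to the glycosylated P1)
#'   or "afterX".
#' @export
stceRule <- function(scissile = c("beforeX", "afterX")) {
  scissile <- match.arg(scissile)
  enzymeRule("StcE", function(residues, glycosylated, glycans, p) {
    n <- length(residues)
    if (scissile == "beforeX") {
      # P1 = p-1 glycosylated S/T, X = p, P2' = p+1 is S/T
      p + 1L <= n &&
        residues[p - 1L] %in% c("S", "T") && glycosylated[p - 1L] &&
        residues[p + 1L] %in% c("S", "T")
    } else {
      # motif positions p-2 (S/T*), p-1 (X), p (S/T)
      p - 2L >= 1L &&
        residues[p - 2L] %in% c("S", "T") && glycosylated[p - 2L] &&
        residues[p] %in% c("S", "T")
    }
  })
}

#' Digest a glycoprotein with an O-glycoprotease rule
#'
#' Cleaves at every position satisfying the rule and emits products with
#' 0..\code{missedCleavages} internal uncleaved sites.
#'
#' @param glycoprotein a \code{syntheticGlycoprotein} (or any list with
#'   \code{sequence} and \code{siteGlycans}).
#' @param rule an \code{enzymeRule}.
#' @param missedCleavages maximum internal missed cleavages.
#' @return data.frame with columns start, end, peptide, nMissed, nGlycans;
#'   the cleavage positions are attached as attribute \code{cleavages}.
#' @export
digest <- function(glycoprotein, rule, missedCleavages = 0L) {
  stopifnot(inherits(rule, "enzymeRule"))
  residues <- strsplit(glycoprotein$sequence, "")[[1]]
  n <- length(residues)
  glycosylated <- rep(FALSE, n)
  glycosylated[as.integer(names(glycoprotein$siteGlycans))] <- TRUE
  cuts <- Filter(function(p)
    isTRUE(rule$sitePredicate(residues, glycosylated,
                              glycoprotein$siteGlycans, p)), 2:n)
  cuts <- as.integer(cuts)
  bounds <- c(1L, cuts, n + 1L)
  rows <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in (i + 1L):length(bounds)) {
      miss <- j - i - 1L
      if (miss > missedCleavages) break
      start <- bounds[i]
      end <- bounds[j] - 1L
      nG <- sum(glycosylated[start:end])
      rows[[length(rows) + 1L]] <- data.frame(
        start = start, end = end,
        peptide = paste(residues[start:end], collapse = ""),
        nMissed = miss, nGlycans = nG, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "cleavages") <- cuts
  attr(out, "enzyme") <- rule$name
  out
}

#' Build a \linkS4class{Glycopeptide} from a digest product
#'
#' @param glycoprotein a \code{syntheticGlycoprotein}.
#' @param start,end 1-based inclusive protein coordinates.
#' @return A \linkS4class{Glycopeptide} with glycans mapped into peptide
#'   coordinates.
#' @export
glycopeptideFromRegion <- function(glycoprotein, start, end) {
  pos <- as.integer(names(glycoprotein$siteGlycans))
  keep <- pos >= start & pos <= end
  sg <- glycoprotein$siteGlycans[keep]
  names(sg) <- as.character(pos[keep] - start + 1L)
  glycopeptide(substr(glycoprotein$sequence, start, end), siteGlycans = sg,
               proteinId = glycoprotein$id, proteinOffset = start)
}

#' Shuffle a glycopeptide sequence (decoy generator)
#'
#' Residues are permuted and the glycan multiset is re-planted on the first
#' Ser/Thr positions of the shuffled sequence, preserving the naked and
#' intact masses while destroying the backbone fragment pattern.
#'
#' @param gp a \linkS4class{Glycopeptide}.
#' @param seed RNG seed.
#' @return a decoy \linkS4class{Glycopeptide}.
#' @export
shuffleGlycopeptide <- function(gp, seed) {
  .withSeed(seed, {
    res <- .residues(gp)
    shuffled <- sample(res)
    st <- which(shuffled %in% c("S", "T"))
    glycans <- unname(gp@siteGlycans)
    if (length(glycans) > length(st)) {
      # ensure enough S/T sites by converting leading residues
      need <- length(glycans) - length(st)
      nonst <- which(!shuffled %in% c("S", "T"))[seq_len(need)]
      shuffled[nonst] <- "T"
      st <- which(shuffled %in% c("S", "T"))
    }
    names(glycans) <- as.character(st[seq_along(glycans)])
    glycopeptide(paste(shuffled, collapse = ""), siteGlycans = glycans,
                 proteinId = paste0(gp@proteinId, "_decoy"),
                 proteinOffset = gp@proteinOffset)
  })
}

## ---- run generator ---------------------------------------------------------

.pickCharge <- function(neutralMass) {
  for (z in 2:6) if (.mzFromNeutral(neutralMass, z) <= 1500) return(z)
  6L
}

#' Generate a synthetic LC-MS run from glycopeptides
#'
#' HCD spectra contain oxonium fingerprint ions scaled by glycan content
#' (NeuAc ions only when sialylated; the 407 m/z di-HexNAc ion and an
#' elevated 138/144 ratio only when a single glycan carries two or more
#' HexNAc), b/y backbone ions with dropout, and Y0. An ETD spectrum is
#' generated only when the oxonium-fingerprint trigger fires on the synthetic
#' HCD scan. MS1 traces are Gaussian elution peaks with isotope envelopes at
#' the planted abundances.
#'
#' @param glycopeptides list of \linkS4class{Glycopeptide}.
#' @param seed RNG seed.
#' @param abundances planted total abundances (one per glycopeptide; default
#'   all 1000).
#' @param dropout per-ion dropout probability in [0, 1) for backbone
#'   fragments.
#' @param mzJitterPpm Gaussian m/z error (ppm) applied to fragment peaks.
#' @param rtStart,rtSpacing retention-time layout in minutes.
#' @param elutionSigma Gaussian elution peak width (min).
#' @return list with \code{spectra} (list of \linkS4class{Spectrum}),
#'   \code{traces} (long-format MS1 data.frame), \code{candidates}
#'   (data.frame scanId, peptide, proteinOffset, glycanMultiset) and
#'   \code{truth}.
#' @export
makeRun <- function(glycopeptides, seed = 1L, abundances = NULL,
                    dropout = 0.1, mzJitterPpm = 0, rtStart = 10,
                    rtSpacing = 1.5, elutionSigma = 0.2) {
  stopifnot(dropout >= 0, dropout < 1)
  if (is.null(abundances)) abundances <- rep(1000, length(glycopeptides))
  stopifnot(length(abundances) == length(glycopeptides))
  .withSeed(seed, {
    spectra <- list()
    traceRows <- list()
    cand <- list()
    truth <- list()
    for (i in seq_along(glycopeptides)) {
      gp <- glycopeptides[[i]]
      M <- glycopeptideMass(gp)
      z <- .pickCharge(M)
      rt <- rtStart + (i - 1L) * rtSpacing
      scanHcd <- sprintf("s%04d_hcd", i)

      glycans <- gp@siteGlycans
      nHexNAc <- sum(vapply(glycans, function(g) g@counts["N"], integer(1)))
      nNeuAc <- sum(vapply(glycans, function(g) g@counts["A"], integer(1)))
      multiHexNAc <- any(vapply(glycans, function(g) g@counts["N"] >= 2L,
                                logical(1)))

      mzs <- numeric(); ints <- numeric()
      addPeak <- function(mz, int) {
        mzs <<- c(mzs, mz * (1 + stats::rnorm(1) * mzJitterPpm * 1e-6))
        ints <<- c(ints, int)
      }
      if (nHexNAc > 0L) {
        ox <- 800 * min(nHexNAc, 3L)
        addPeak(126.055, 0.4 * ox); addPeak(168.065, 0.3 * ox)
        addPeak(186.076, 0.5 * ox); addPeak(204.086, ox)
        if (multiHexNAc) {
          addPeak(138.055, 0.7 * ox); addPeak(144.07, 0.35 * ox)
          addPeak(.OXONIUM_DIHEXNAC, 0.3 * ox)
        } else {
          addPeak(138.055, 0.5 * ox); addPeak(144.07, 0.5 * ox)
        }
        if (nNeuAc > 0L) { addPeak(274.092, 0.4 * ox); addPeak(292.103, 0.6 * ox) }
      }
      fragZ <- seq_len(max(1L, min(2L, z - 1L)))
      theoBY <- theoreticalFragments(gp, series = c("b", "y"),
                                     maxCharge = max(fragZ), includeY0 = FALSE)
      keep <- stats::runif(nrow(theoBY)) >= dropout
      for (r in which(keep))
        addPeak(theoBY$mz[r], stats::runif(1, 100, 500))
      for (zz in seq_len(z))    # Y0 at every charge
        addPeak(.mzFromNeutral(peptideMass(gp), zz), stats::runif(1, 150, 400))

      hcd <- spectrum(mzs, ints, scanId = scanHcd, activation = "HCD",
                      precursorMz = .mzFromNeutral(M, z), precursorCharge = z,
                      retentionTime = rt)
      spectra[[scanHcd]] <- hcd

      etdId <- NA_character_
      if (shouldTriggerEtd(hcd)$trigger) {
        etdId <- sprintf("s%04d_etd", i)
        theoCZ <- theoreticalFragments(gp, series = c("c", "z"),
                                       maxCharge = max(fragZ),
                                       includeY0 = FALSE)
        keepCZ <- stats::runif(nrow(theoCZ)) >= dropout
        emz <- theoCZ$mz[keepCZ] *
          (1 + stats::rnorm(sum(keepCZ)) * mzJitterPpm * 1e-6)
        eint <- stats::runif(sum(keepCZ), 100, 500)
        spectra[[etdId]] <- spectrum(emz, eint, scanId = etdId,
                                     activation = "EThcD",
                                     precursorMz = .mzFromNeutral(M, z),
                                     precursorCharge = z, retentionTime = rt)
      }

      # MS1 traces: Gaussian elution peaks on the isotope channels
      chan <- glycoformChannels(gp, z)
      w <- 0.6^chan$isotope
      w <- w / sum(w)
      grid <- seq(rt - 1, rt + 1, by = 0.02)
      for (k in seq_len(nrow(chan))) {
        traceRows[[length(traceRows) + 1L]] <- data.frame(
          mz = chan$mz[k], charge = chan$charge[k], rt = grid,
          intensity = abundances[i] * w[k] *
            stats::dnorm(grid, mean = rt, sd = elutionSigma))
      }

      gstr <- sort(vapply(glycans, formatComposition, character(1)))
      cand[[i]] <- data.frame(
        scanId = scanHcd, etdScanId = etdId, peptide = gp@sequence,
        proteinOffset = gp@proteinOffset,
        glycanMultiset = paste(gstr, collapse = "+"),
        stringsAsFactors = FALSE)
      truth[[i]] <- list(glycopeptide = gp, abundance = abundances[i],
                         charge = z, rt = rt, hcdScan = scanHcd,
                         etdScan = etdId)
    }
    list(spectra = spectra, traces = do.call(rbind, traceRows),
         candidates = do.call(rbind, cand), truth = truth)
  })
}

## ---- physics generators ----------------------------------------------------

## concentration parameter of the exp(kappa * cos) deflection density whose
## mean cosine (Langevin function) equals the target
.solveKappa <- function(meanCos) {
  if (meanCos <= 0) return(0)
  langevin <- function(k) 1 / tanh(k) - 1 / k
  stats::uniroot(function(k) langevin(k) - meanCos,
                 lower = 1e-8, upper = 1e8, tol = 1e-12)$root
}

#' Generate a worm-like-chain trajectory of known persistence length
#'
#' Each frame is an independent chain whose successive bond deflections are
#' drawn so that the mean cosine of the deflection angle equals
#' exp(-lb/lp); bond length is fixed at lb. This makes the generator an
#' analytic oracle for the persistence-length estimator.
#'
#' @param seed RNG seed.
#' @param nMonomers number of monomers (one CA-like atom each).
#' @param lb bond length in \enc{Å}{Angstrom}.
#' @param lp planted persistence length in \enc{Å}{Angstrom}.
#' @param nFrames number of independent frames.
#' @param replicaId replica identifier.
#' @return A \linkS4class{PolymerTrajectory} with attribute \code{truth}
#'   (list with lp, lb).
#' @export
makeWlcTrajectory <- function(seed, nMonomers = 200L, lb = 3.8, lp = 100,
                              nFrames = 2000L, replicaId = "rep1") {
  stopifnot(lp > 0, lb > 0, nMonomers >= 3L, nFrames >= 1L)
  meanCos <- exp(-lb / lp)
  kappa <- .solveKappa(meanCos)
  .withSeed(seed, {
    nf <- nFrames
    coords <- array(0, dim = c(nMonomers, 3L, nf))
    # initial bond directions: uniform on the sphere, one per frame
    u <- matrix(stats::rnorm(nf * 3L), ncol = 3L)
    u <- u / sqrt(rowSums(u^2))
    pos <- matrix(0, nrow = nf, ncol = 3L)
    for (m in 2:nMonomers) {
      pos <- pos + lb * u
      coords[m, , ] <- t(pos)
      if (m == nMonomers) break
      # sample deflection cosines (inverse CDF of exp(kappa * c) on [-1, 1])
      U <- stats::runif(nf)
      cosT <- if (kappa < 1e-8) 2 * U - 1
      else 1 + log(U + (1 - U) * exp(-2 * kappa)) / kappa
      sinT <- sqrt(pmax(0, 1 - cosT^2))
      phi <- stats::runif(nf, 0, 2 * pi)
      # orthonormal frame around each current direction
      ref <- matrix(rep(c(1, 0, 0), each = nf), ncol = 3L)
      swap <- abs(u[, 1L]) > 0.9
      ref[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3L)
      e1 <- cbind(u[, 2L] * ref[, 3L] - u[, 3L] * ref[, 2L],
                  u[, 3L] * ref[, 1L] - u[, 1L] * ref[, 3L],
                  u[, 1L] * ref[, 2L] - u[, 2L] * ref[, 1L])
      e1 <- e1 / sqrt(rowSums(e1^2))
      e2 <- cbind(u[, 2L] * e1[, 3L] - u[, 3L] * e1[, 2L],
                  u[, 3L] * e1[, 1L] - u[, 1L] * e1[, 3L],
                  u[, 1L] * e1[, 2L] - u[, 2L] * e1[, 1L])
      u <- cosT * u + sinT * (cos(phi) * e1 + sin(phi) * e2)
      u <- u / sqrt(rowSums(u^2))
    }
    traj <- polymerTrajectory(
      coords,
      data.frame(resid = seq_len(nMonomers), name = "CA",
                 element = "C", mass = 12.011, stringsAsFactors = FALSE),
      replicaId = replicaId)
    attr(traj, "truth") <- list(lp = lp, lb = lb)
    traj
  })
}

#' Generate a one-phase exponential SPR dissociation sensorgram
#'
#' Y(t) = (Y0 - NS) * exp(-K * t) + NS plus Gaussian noise.
#'
#' @param seed RNG seed.
#' @param K planted dissociation rate koff (s^-1, > 0).
#' @param Y0 binding at time zero (RU).
#' @param NS nonspecific plateau (RU).
#' @param times sampling times in seconds (re-zeroed dissociation phase).
#' @param sigma Gaussian noise SD in RU (>= 0).
#' @return data.frame with columns time, response and attribute \code{truth}.
#' @export
makeSprSensorgram <- function(seed, K, Y0 = 100, NS = 10,
                              times = seq(0, 120, by = 1), sigma = 0) {
  stopifnot(K > 0, sigma >= 0)
  .withSeed(seed, {
    y <- (Y0 - NS) * exp(-K * times) + NS
    if (sigma > 0) y <- y + stats::rnorm(length(times), sd = sigma)
    out <- data.frame(time = times, response = y)
    attr(out, "truth") <- list(K = K, Y0 = Y0, NS = NS, sigma = sigma)
    out
  })
}
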