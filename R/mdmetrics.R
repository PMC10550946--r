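## Mucin-domain polymer metrics on coordinate trajectories: normalized
## end-to-end distance, bending angle, persistence length, height per glycan.

.ELEMENT_WEIGHTS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                      S = 32.06, P = 30.974)

.elementFromName <- function(name) {
  # PDB-style atom names: strip digits/primes, first letter is the element
  # for the organic set used here
  el <- substr(gsub("[^A-Za-z]", "", name), 1L, 1L)
  toupper(el)
}

#' Construct a polymer trajectory
#'
#' @param coords numeric array (nAtoms, 3, nFrames), or a list of
#'   nAtoms x 3 per-frame matrices.
#' @param atoms data.frame with columns resid and name; element and mass are
#'   filled from standard atomic weights when missing.
#' @param replicaId replica identifier.
#' @return A \linkS4class{PolymerTrajectory}.
#' @export
polymerTrajectory <- function(coords, atoms, replicaId = "rep1") {
  if (is.list(coords))
    coords <- array(unlist(coords),
                    dim = c(nrow(coords[[1L]]), 3L, length(coords)))
  if (is.null(atoms$element))
    atoms$element <- vapply(as.character(atoms$name), .elementFromName,
                            character(1))
  if (is.null(atoms$mass)) {
    atoms$mass <- .ELEMENT_WEIGHTS[atoms$element]
    if (anyNA(atoms$mass))
      stop("unknown element(s): ",
           paste(unique(atoms$element[is.na(atoms$mass)]), collapse = ", "))
  }
  new("PolymerTrajectory", coords = coords, atoms = atoms,
      replicaId = replicaId)
}

setMethod("show", "PolymerTrajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("PolymerTrajectory %s: %d atoms, %d frames, residues %d..%d\n",
              object@replicaId, d[1L], d[3L],
              min(object@atoms$resid), max(object@atoms$resid)))
})

#' @rdname polymerTrajectory
#' @param traj a \linkS4class{PolymerTrajectory}.
#' @export
nFrames <- function(traj) dim(traj@coords)[3L]

#' Define a mucin-domain selection
#'
#' @param polymerRange c(first, last) residue ids of the backbone polymer used
#'   for the persistence length.
#' @param bendingAnchors c(first, middle, last) residue ids for the bending
#'   angle.
#' @param endAnchors c(first, last) residue ids for the end-to-end distance
#'   (defaults to the polymer range ends).
#' @param nGlycans number of glycans in the mucin domain.
#' @param nMucinResidues number of protein residues in the mucin domain
#'   (defaults to the polymer range width).
#' @return A \linkS4class{MucinSelection}.
#' @export
mucinSelection <- function(polymerRange, bendingAnchors = NULL,
                           endAnchors = NULL, nGlycans = 1L,
                           nMucinResidues = NULL) {
  polymerRange <- as.integer(polymerRange)
  if (is.null(endAnchors)) endAnchors <- polymerRange
  if (is.null(bendingAnchors))
    bendingAnchors <- c(polymerRange[1L],
                        as.integer(floor(mean(polymerRange))), polymerRange[2L])
  if (is.null(nMucinResidues))
    nMucinResidues <- polymerRange[2L] - polymerRange[1L] + 1L
  new("MucinSelection", polymerRange = polymerRange,
      bendingAnchors = as.integer(bendingAnchors),
      endAnchors = as.integer(endAnchors),
      nGlycans = as.integer(nGlycans),
      nMucinResidues = as.integer(nMucinResidues))
}

## mass-weighted center of mass of one residue across all frames;
## returns 3 x nFrames matrix
.residueCom <- function(traj, resid) {
  sel <- which(traj@atoms$resid == resid)
  if (!length(sel)) stop("residue ", resid, " not found in trajectory")
  w <- traj@atoms$mass[sel]
  xyz <- traj@coords[sel, , , drop = FALSE]
  apply(xyz, c(2L, 3L), function(v) sum(v * w) / sum(w))
}

#' Normalized end-to-end distance per frame
#'
#' Distance between the centers of mass of the two end-anchor residues,
#' divided by the number of protein residues in the mucin domain
#' (\enc{Å}{Angstrom} per residue).
#'
#' @param traj a \linkS4class{PolymerTrajectory}.
#' @param sel a \linkS4class{MucinSelection}.
#' @return numeric vector, one value per frame.
#' @export
endToEndSeries <- function(traj, sel) {
  a <- .residueCom(traj, sel@endAnchors[1L])
  b <- .residueCom(traj, sel@endAnchors[2L])
  sqrt(colSums((a - b)^2)) / sel@nMucinResidues
}

#' Bending angle per frame
#'
#' Angle (degrees, in [0, 180]) between the vector from the middle anchor to
#' the first anchor and the vector from the middle anchor to the last anchor,
#' using residue centers of mass. Frames with a zero-length vector yield NA.
#'
#' @param traj a \linkS4class{PolymerTrajectory}.
#' @param sel a \linkS4class{MucinSelection}.
#' @param breaks histogram breaks in degrees.
#' @return list with \code{angles} (numeric per frame) and \code{histogram}
#'   (data.frame mid, density; a normalized density histogram).
#' @export
bendingAngleSeries <- function(traj, sel, breaks = seq(0, 180, by = 5)) {
  anchors <- sel@bendingAnchors
  f <- .residueCom(traj, anchors[1L])
  m <- .residueCom(traj, anchors[2L])
  l <- .residueCom(traj, anchors[3L])
  v1 <- f - m
  v2 <- l - m
  n1 <- sqrt(colSums(v1^2))
  n2 <- sqrt(colSums(v2^2))
  cosang <- colSums(v1 * v2) / (n1 * n2)
  cosang[n1 == 0 | n2 == 0] <- NA_real_
  angles <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  h <- graphics::hist(angles[!is.na(angles)], breaks = breaks, plot = FALSE)
  list(angles = angles,
       histogram = data.frame(mid = h$mids, density = h$density))
}

## ordered backbone chain (N, CA, C per residue) coordinates for one frame
.chainAtomIndices <- function(traj, polymerRange) {
  at <- traj@atoms
  keep <- which(at$resid >= polymerRange[1L] & at$resid <= polymerRange[2L] &
                  at$name %in% c("N", "CA", "C"))
  if (!length(keep)) stop("no backbone atoms (N, CA, C) in polymer range")
  ord <- order(at$resid[keep], match(at$name[keep], c("N", "CA", "C")))
  keep[ord]
}

#' Bond-vector autocorrelation of a polymer chain
#'
#' Builds the ordered backbone chain (N, CA, C atoms of the polymer residue
#' range), computes unit bond vectors between consecutive chain atoms, and
#' returns C(n), the average over frames and positions of the cosine of the
#' angle between bonds i and i+n. C(0) = 1 exactly.
#'
#' @param traj a \linkS4class{PolymerTrajectory}.
#' @param sel a \linkS4class{MucinSelection}.
#' @param frameWindow number of final frames used (default 1000).
#' @param nMax maximum lag (default half the number of bonds).
#' @return list with \code{n}, \code{C}, \code{lb} (mean bond length) and
#'   \code{nBonds}.
#' @export
bondAutocorrelation <- function(traj, sel, frameWindow = 1000L, nMax = NULL) {
  idx <- .chainAtomIndices(traj, sel@polymerRange)
  if (length(idx) < 3L) stop("need at least 2 bonds in the polymer chain")
  nf <- nFrames(traj)
  if (nf < frameWindow)
    warning("fewer frames (", nf, ") than requested window (", frameWindow,
            "); using all frames")
  frames <- seq.int(max(1L, nf - frameWindow + 1L), nf)
  nBonds <- length(idx) - 1L
  if (is.null(nMax)) nMax <- nBonds %/% 2L
  nMax <- min(nMax, nBonds - 1L)

  sums <- numeric(nMax + 1L)
  counts <- numeric(nMax + 1L)
  lbSum <- 0
  for (f in frames) {
    xyz <- traj@coords[idx, , f]
    bonds <- diff(xyz)
    lens <- sqrt(rowSums(bonds^2))
    lbSum <- lbSum + mean(lens)
    u <- bonds / lens
    for (lag in 0:nMax) {
      i <- seq_len(nBonds - lag)
      sums[lag + 1L] <- sums[lag + 1L] + sum(rowSums(u[i, , drop = FALSE] *
                                                       u[i + lag, , drop = FALSE]))
      counts[lag + 1L] <- counts[lag + 1L] + length(i)
    }
  }
  list(n = 0:nMax, C = sums / counts, lb = lbSum / length(frames),
       nBonds = nBonds)
}

#' Persistence length of a mucin-domain polymer
#'
#' Fits the bond autocorrelation to the exponential decay
#' C(n) = exp(-n lb / lp) per replica, by least squares on log C(n) through
#' the origin over lags 1 up to the first lag where C(n) falls below
#' exp(-2) (or half the chain length), restricted to C(n) > 0. A chain with no
#' measurable decorrelation (straight rod) is flagged infinite.
#'
#' @param trajs a \linkS4class{PolymerTrajectory} or a list of them (one per
#'   replica).
#' @param sel a \linkS4class{MucinSelection}.
#' @param frameWindow number of final frames per replica (default 1000).
#' @return list of class \code{persistenceResult} with per-replica lp and lb,
#'   \code{lp} (mean across replicas), \code{sd}, \code{nReplicas}, and fit
#'   diagnostics.
#' @export
persistenceLength <- function(trajs, sel, frameWindow = 1000L) {
  if (is(trajs, "PolymerTrajectory")) trajs <- list(trajs)
  fits <- lapply(trajs, function(traj) {
    ac <- bondAutocorrelation(traj, sel, frameWindow)
    cutoff <- which(ac$C[-1L] < exp(-2))
    nFitMax <- if (length(cutoff)) cutoff[1L] else length(ac$n) - 1L
    fitN <- ac$n[ac$n >= 1L & ac$n <= nFitMax]
    fitC <- ac$C[match(fitN, ac$n)]
    pos <- fitC > 0
    fitN <- fitN[pos]
    fitC <- fitC[pos]
    if (length(fitN) < 1L)
      return(list(lp = 0, lb = ac$lb, slope = -Inf, nFit = 0L, ac = ac))
    slope <- sum(fitN * log(fitC)) / sum(fitN^2)
    lp <- if (slope >= 0) Inf else -ac$lb / slope
    list(lp = lp, lb = ac$lb, slope = slope, nFit = length(fitN), ac = ac)
  })
  lps <- vapply(fits, `[[`, numeric(1), "lp")
  out <- list(
    lp = mean(lps), sd = if (length(lps) > 1L) stats::sd(lps) else 0,
    perReplica = lps,
    lb = mean(vapply(fits, `[[`, numeric(1), "lb")),
    nReplicas = length(fits), infinite = any(!is.finite(lps)), fits = fits)
  class(out) <- "persistenceResult"
  out
}

#' @export
print.persistenceResult <- function(x, ...) {
  cat(sprintf("Persistence length: %.1f +/- %.1f A over %d replica(s) (lb = %.2f A)\n",
              x$lp, x$sd, x$nReplicas, x$lb))
  invisible(x)
}

#' Height per glycan (total vs effective glycosylation)
#'
#' The mucin-domain backbone end-to-end length (center of mass of the first to
#' the last polymer residue) divided by the number of glycans. Mode
#' "outstretched" uses the first frame of each replica (total glycosylation);
#' mode "equilibrated" uses the mean over the final frame window of each
#' replica (effective glycosylation). The SD is across replicas.
#'
#' @param trajs a \linkS4class{PolymerTrajectory} or list of replicas.
#' @param sel a \linkS4class{MucinSelection}.
#' @param mode "outstretched" or "equilibrated".
#' @param frameWindow final frames per replica for the equilibrated mode.
#' @return list with \code{heightPerGlycan}, \code{sd} and \code{perReplica}.
#' @export
heightPerGlycan <- function(trajs, sel, mode = c("outstretched", "equilibrated"),
                            frameWindow = 1000L) {
  mode <- match.arg(mode)
  if (is(trajs, "PolymerTrajectory")) trajs <- list(trajs)
  per <- vapply(trajs, function(traj) {
    a <- .residueCom(traj, sel@polymerRange[1L])
    b <- .residueCom(traj, sel@polymerRange[2L])
    len <- sqrt(colSums((a - b)^2))
    nf <- length(len)
    if (mode == "outstretched") len[1L]
    else mean(len[seq.int(max(1L, nf - frameWindow + 1L), nf)])
  }, numeric(1)) / sel@nGlycans
  list(heightPerGlycan = mean(per),
       sd = if (length(per) > 1L) stats::sd(per) else 0,
       perReplica = per)
}

## ---- trajectory readers ----------------------------------------------------

#' Read a multi-model PDB file as a polymer trajectory
#'
#' @param path PDB file path (MODEL/ENDMDL frames).
#' @param replicaId replica identifier.
#' @return A \linkS4class{PolymerTrajectory}.
#' @export
readTrajectoryPDB <- function(path, replicaId = "rep1") {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  at <- pdb$atom
  xyz <- pdb$xyz                       # nFrames x (3 * nAtoms)
  nf <- nrow(xyz)
  na <- nrow(at)
  coords <- array(NA_real_, dim = c(na, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  polymerTrajectory(coords,
                    data.frame(resid = at$resno, name = at$elety,
                               stringsAsFactors = FALSE),
                    replicaId = replicaId)
}

#' Read a DCD trajectory with a PDB topology
#'
#' @param dcdPath DCD file path.
#' @param topologyPdb single-frame PDB giving the atom table.
#' @param replicaId replica identifier.
#' @return A \linkS4class{PolymerTrajectory}.
#' @export
readTrajectoryDCD <- function(dcdPath, topologyPdb, replicaId = "rep1") {
  pdb <- bio3d::read.pdb(topologyPdb)
  xyz <- bio3d::read.dcd(dcdPath, verbose = FALSE)
  at <- pdb$atom
  nf <- nrow(xyz)
  na <- nrow(at)
  coords <- array(NA_real_, dim = c(na, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  polymerTrajectory(coords,
                    data.frame(resid = at$resno, name = at$elety,
                               stringsAsFactors = FALSE),
                    replicaId = replicaId)
}
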