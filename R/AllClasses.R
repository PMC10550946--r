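#' @import methods
NULL

## ---- mass constants (monoisotopic, Da) ------------------------------------

.ELEMENT_MASS <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

.massFromFormula <- function(counts) {
  sum(.ELEMENT_MASS[names(counts)] * counts)
}

#' Physical constants used throughout the package
#'
#' Proton mass, water, ammonia and related monoisotopic constants, all in Da,
#' computed from elemental monoisotopic masses.
#' @keywords internal
.CONST <- list(
  proton   = 1.007276466879,
  water    = .massFromFormula(c(H = 2, O = 1)),
  ammonia  = .massFromFormula(c(N = 1, H = 3)),
  nh2      = .massFromFormula(c(N = 1, H = 2)),
  # z-dot (radical z) neutral offset over the residue sum: H2O - NH2
  zdot     = .massFromFormula(c(H = 2, O = 1)) - .massFromFormula(c(N = 1, H = 2)),
  # carbamidomethyl (fixed on Cys), C2H3NO
  cam      = .massFromFormula(c(C = 2, H = 3, N = 1, O = 1)),
  # Met oxidation, +O
  ox       = .massFromFormula(c(O = 1)),
  # neutral loss of the oxidized Met side chain, CH4SO
  metOxLoss = .massFromFormula(c(C = 1, H = 4, S = 1, O = 1)),
  # 13C - 12C spacing used for isotope channels
  isotope  = 1.00335
)

## Monosaccharide residue masses from elemental formulas:
## HexNAc C8H13NO5, Hex C6H10O5, NeuAc C11H17NO8, dHex (Fuc) C6H10O4
.GLYCAN_MASS <- c(
  N = .massFromFormula(c(C = 8,  H = 13, N = 1, O = 5)),
  H = .massFromFormula(c(C = 6,  H = 10, O = 5)),
  A = .massFromFormula(c(C = 11, H = 17, N = 1, O = 8)),
  F = .massFromFormula(c(C = 6,  H = 10, O = 4))
)

## Standard amino-acid residue monoisotopic masses (unmodified side chains)
.AA_MASS <- c(
  G = 57.02146372, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841391, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

.AMINO_ACIDS <- names(.AA_MASS)

## HexNAc/NeuAc oxonium fingerprint ions used for the ETD trigger (m/z)
.FINGERPRINT_MZ <- c(126.055, 138.055, 144.07, 168.065, 186.076,
                     204.086, 274.092, 292.103)

## diagnostic oxonium ions used during validation (m/z)
.OXONIUM_HEXNAC  <- 204.0867     # HexNAc + proton
.OXONIUM_DIHEXNAC <- 407.1660    # 2x HexNAc + proton

## ---- S4 classes ------------------------------------------------------------

#' Glycan composition
#'
#' A monosaccharide count vector over HexNAc (N), hexose (H), NeuAc (A) and
#' fucose (F). The all-zero composition is the "no glycan" element. Mass is a
#' deterministic function of the counts.
#'
#' @slot counts named integer vector with entries N, H, A, F (all >= 0).
#' @export
setClass("GlycanComposition", representation(counts = "integer"))

setValidity("GlycanComposition", function(object) {
  cts <- object@counts
  if (length(cts) != 4L || !identical(names(cts), c("N", "H", "A", "F")))
    return("counts must be a length-4 integer vector named N, H, A, F")
  if (anyNA(cts) || any(cts < 0L))
    return("all monosaccharide counts must be non-negative integers")
  TRUE
})

#' Glycopeptide
#'
#' A peptide sequence with per-site glycan assignments. Carbamidomethyl Cys is
#' treated as a fixed modification; oxidized Met positions are variable.
#'
#' @slot sequence single-letter amino-acid string.
#' @slot siteGlycans named list of \linkS4class{GlycanComposition}; names are
#'   1-based positions within the peptide, each pointing at Ser or Thr.
#' @slot oxMetPositions integer positions of oxidized Met residues.
#' @slot proteinId parent protein identifier.
#' @slot proteinOffset 1-based start of the peptide in the parent protein.
#' @export
setClass("Glycopeptide", representation(
  sequence       = "character",
  siteGlycans    = "list",
  oxMetPositions = "integer",
  proteinId      = "character",
  proteinOffset  = "integer"
))

setValidity("Glycopeptide", function(object) {
  seq <- object@sequence
  if (length(seq) != 1L || !nzchar(seq)) return("sequence must be a nonempty string")
  res <- strsplit(seq, "")[[1]]
  if (!all(res %in% .AMINO_ACIDS)) {
    bad <- setdiff(unique(res), .AMINO_ACIDS)
    return(paste0("unknown residue(s): ", paste(bad, collapse = ", ")))
  }
  sg <- object@siteGlycans
  if (length(sg)) {
    pos <- suppressWarnings(as.integer(names(sg)))
    if (anyNA(pos)) return("siteGlycans names must be integer positions")
    if (any(pos < 1L | pos > length(res))) return("glycan position outside peptide")
    if (!all(res[pos] %in% c("S", "T")))
      return("glycan positions must point at Ser or Thr")
    if (!all(vapply(sg, is, logical(1), class2 = "GlycanComposition")))
      return("siteGlycans entries must be GlycanComposition objects")
  }
  if (length(object@oxMetPositions) &&
      !all(res[object@oxMetPositions] == "M"))
    return("oxMetPositions must point at Met residues")
  TRUE
})

#' Centroided MS2 spectrum
#'
#' @slot scanId scan identifier.
#' @slot activation one of "HCD", "ETD", "EThcD".
#' @slot precursorMz precursor m/z.
#' @slot precursorCharge precursor charge state.
#' @slot retentionTime retention time in minutes.
#' @slot peaks two-column matrix (mz, intensity), sorted by m/z.
#' @export
setClass("Spectrum", representation(
  scanId          = "character",
  activation      = "character",
  precursorMz     = "numeric",
  precursorCharge = "integer",
  retentionTime   = "numeric",
  peaks           = "matrix"
))

setValidity("Spectrum", function(object) {
  if (!object@activation %in% c("HCD", "ETD", "EThcD"))
    return("activation must be HCD, ETD or EThcD")
  pk <- object@peaks
  if (ncol(pk) != 2L) return("peaks must have two columns (mz, intensity)")
  if (nrow(pk)) {
    if (is.unsorted(pk[, 1L])) return("peaks must be sorted by m/z")
    if (any(pk[, 2L] < 0)) return("intensities must be >= 0")
    if (max(pk[, 2L]) <= 0) return("base peak intensity must be > 0")
  }
  TRUE
})

#' Polymer trajectory
#'
#' Frames of Cartesian coordinates (\enc{Å}{Angstrom}) for a fixed atom set.
#'
#' @slot coords numeric array of dimension (nAtoms, 3, nFrames).
#' @slot atoms data.frame with columns resid, name, element, mass.
#' @slot replicaId replica identifier.
#' @export
setClass("PolymerTrajectory", representation(
  coords    = "array",
  atoms     = "data.frame",
  replicaId = "character"
))

setValidity("PolymerTrajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2L] != 3L)
    return("coords must be an (nAtoms, 3, nFrames) array")
  if (d[3L] < 1L) return("at least one frame is required")
  at <- object@atoms
  need <- c("resid", "name", "element", "mass")
  if (!all(need %in% names(at)))
    return("atoms must have columns resid, name, element, mass")
  if (nrow(at) != d[1L]) return("atom table and coordinate array disagree")
  if (any(at$mass <= 0)) return("atom masses must be positive")
  TRUE
})

#' Mucin-domain selection
#'
#' Residue anchors defining a mucin-domain polymer on a trajectory: the
#' backbone residue range used for the persistence-length chain, the three
#' anchors for the bending angle, the two end-to-end anchors, and the glycan
#' and residue counts used for normalization.
#'
#' @slot polymerRange integer c(first, last), 1-based residue ids.
#' @slot bendingAnchors integer c(first, middle, last) residue ids.
#' @slot endAnchors integer c(first, last) residue ids for end-to-end distance.
#' @slot nGlycans number of glycans in the mucin domain.
#' @slot nMucinResidues number of protein residues in the mucin domain.
#' @export
setClass("MucinSelection", representation(
  polymerRange   = "integer",
  bendingAnchors = "integer",
  endAnchors     = "integer",
  nGlycans       = "integer",
  nMucinResidues = "integer"
))

setValidity("MucinSelection", function(object) {
  b <- object@bendingAnchors
  if (length(b) != 3L || !(b[1L] < b[2L] && b[2L] < b[3L]))
    return("bendingAnchors must be three increasing residue ids")
  if (length(object@polymerRange) != 2L ||
      object@polymerRange[1L] >= object@polymerRange[2L])
    return("polymerRange must be c(first, last) with first < last")
  if (length(object@endAnchors) != 2L)
    return("endAnchors must be two residue ids")
  if (object@nGlycans < 1L) return("nGlycans must be >= 1")
  if (object@nMucinResidues < 1L) return("nMucinResidues must be >= 1")
  TRUE
})

#' Validation decision
#'
#' Outcome of the manual-validation rulebook for one glycopeptide/spectrum
#' pair: overall status, per-rule evidence, and per-site localization status.
#'
#' @slot status "accept", "reject" or "ambiguous".
#' @slot reasons data.frame with columns rule, pass, detail.
#' @slot siteStatus named character vector, one of "localized",
#'   "unlocalized", "contradicted" per candidate site.
#' @slot siteGlycans named list of glycan composition strings assigned per
#'   site (after any core-1 decomposition of unresolved multi-site glycans).
#' @export
setClass("ValidationDecision", representation(
  status      = "character",
  reasons     = "data.frame",
  siteStatus  = "character",
  siteGlycans = "list"
))

setValidity("ValidationDecision", function(object) {
  if (!object@status %in% c("accept", "reject", "ambiguous"))
    return("status must be accept, reject or ambiguous")
  if (length(object@siteStatus) &&
      !all(object@siteStatus %in% c("localized", "unlocalized", "contradicted")))
    return("siteStatus values must be localized, unlocalized or contradicted")
  TRUE
})
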