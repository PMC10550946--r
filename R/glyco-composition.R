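## Monosaccharide composition algebra: parsing, masses, residual-mass
## enumeration, core-type classification and the multi-site decomposition rule.

#' Create a glycan composition
#'
#' @param N,H,A,F counts of HexNAc (GalNAc), hexose (galactose), NeuAc
#'   (sialic acid) and fucose residues.
#' @return A \linkS4class{GlycanComposition}.
#' @examples
#' glycanComposition(N = 1, H = 1)   # core 1 disaccharide
#' @export
glycanComposition <- function(N = 0, H = 0, A = 0, F = 0) {
  cts <- c(N = N, H = H, A = A, F = F)
  if (any(abs(cts - round(cts)) > 1e-9))
    stop("monosaccharide counts must be integers")
  new("GlycanComposition", counts = structure(as.integer(round(cts)),
                                              names = c("N", "H", "A", "F")))
}

#' Parse a composition string such as "H1N1A1"
#'
#' The grammar is a sequence of (letter, count) pairs with letters from
#' {N, H, A, F} in any order, each letter appearing at most once. The empty
#' string denotes the zero ("no glycan") composition.
#'
#' @param text composition string.
#' @return A \linkS4class{GlycanComposition}.
#' @export
parseComposition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(text)) return(glycanComposition())
  tokens <- regmatches(text, gregexpr("[A-Za-z][0-9]*", text))[[1]]
  if (!identical(paste(tokens, collapse = ""), text))
    stop("malformed composition string: '", text, "'")
  cts <- c(N = 0L, H = 0L, A = 0L, F = 0L)
  seen <- character()
  for (tok in tokens) {
    letter <- toupper(substr(tok, 1L, 1L))
    if (!letter %in% names(cts))
      stop("unknown monosaccharide letter '", substr(tok, 1L, 1L),
           "' in '", text, "'")
    if (letter %in% seen)
      stop("letter '", letter, "' repeated in '", text, "'")
    seen <- c(seen, letter)
    num <- substr(tok, 2L, nchar(tok))
    cts[letter] <- if (nzchar(num)) as.integer(num) else 1L
  }
  glycanComposition(N = cts["N"], H = cts["H"], A = cts["A"], F = cts["F"])
}

#' Canonical composition string
#'
#' Letters in the fixed order N, H, A, F with zero counts omitted; the zero
#' composition formats as the empty string. \code{parseComposition} and
#' \code{formatComposition} round-trip.
#'
#' @param comp a \linkS4class{GlycanComposition}.
#' @return character scalar.
#' @export
formatComposition <- function(comp) {
  stopifnot(is(comp, "GlycanComposition"))
  cts <- comp@counts
  nz <- cts > 0L
  paste0(names(cts)[nz], cts[nz], collapse = "")
}

#' Monoisotopic mass of a glycan composition
#'
#' Residue (dehydrated) monoisotopic masses computed from elemental formulas:
#' HexNAc C8H13NO5, Hex C6H10O5, NeuAc C11H17NO8, dHex C6H10O4. The mass is
#' additive under composition addition; the zero composition has mass 0.
#'
#' @param comp a \linkS4class{GlycanComposition} or composition string.
#' @return mass in Da.
#' @export
compositionMass <- function(comp) {
  if (is.character(comp)) comp <- parseComposition(comp)
  stopifnot(is(comp, "GlycanComposition"))
  sum(as.numeric(comp@counts) * .GLYCAN_MASS)
}

#' @describeIn glycanComposition composition addition
#' @param e1,e2 compositions.
#' @export
setMethod("+", signature("GlycanComposition", "GlycanComposition"),
          function(e1, e2) {
            new("GlycanComposition", counts = e1@counts + e2@counts)
          })

setMethod("show", "GlycanComposition", function(object) {
  s <- formatComposition(object)
  cat(sprintf("GlycanComposition %s (%.4f Da)\n",
              if (nzchar(s)) s else "<none>", compositionMass(object)))
})

#' Total monosaccharide count of a composition
#' @param comp a \linkS4class{GlycanComposition}.
#' @export
compositionSize <- function(comp) sum(comp@counts)

#' Enumerate compositions matching a residual mass
#'
#' Exhaustively enumerates all bounded count vectors and returns those whose
#' mass is within \code{tol} of \code{residualMass}, sorted by absolute mass
#' error then canonical string. Supports de novo assignment by matching the
#' difference between a precursor mass and a naked peptide mass to
#' combinations of glycan masses.
#'
#' @param residualMass target mass in Da (>= 0).
#' @param tol absolute tolerance in Da.
#' @param bounds named integer vector of per-monosaccharide maximum counts.
#' @return list of \linkS4class{GlycanComposition}; empty when nothing
#'   matches. The zero composition is returned for residuals near 0.
#' @export
enumerateCompositions <- function(residualMass, tol = 0.02,
                                  bounds = c(N = 6, H = 6, A = 4, F = 3)) {
  stopifnot(residualMass >= 0, tol > 0, all(is.finite(bounds)))
  bounds <- bounds[c("N", "H", "A", "F")]
  grid <- expand.grid(N = 0:bounds["N"], H = 0:bounds["H"],
                      A = 0:bounds["A"], F = 0:bounds["F"])
  mass <- as.matrix(grid) %*% .GLYCAN_MASS[c("N", "H", "A", "F")]
  err <- abs(mass - residualMass)
  hit <- which(err <= tol)
  if (!length(hit)) return(list())
  comps <- lapply(hit, function(i)
    glycanComposition(N = grid$N[i], H = grid$H[i], A = grid$A[i], F = grid$F[i]))
  key <- vapply(comps, formatComposition, character(1))
  comps[order(err[hit], key)]
}

#' Classify a composition into an O-glycan core category
#'
#' Category map: Tn = a single HexNAc with no hexose and at most one NeuAc or
#' fucose (so sialyl-Tn and fucosyl-Tn count as Tn); core 1 = one HexNAc with
#' at least one hexose; core 2 = two or more HexNAc with at least one hexose;
#' everything else (including bare multi-HexNAc compositions) is "other".
#'
#' @param comp a \linkS4class{GlycanComposition} or composition string.
#' @return one of "Tn", "core1", "core2", "other".
#' @export
classifyCore <- function(comp) {
  if (is.character(comp)) comp <- parseComposition(comp)
  cts <- comp@counts
  if (sum(cts) == 0L) stop("no glycan has no core")
  if (cts["N"] == 1L && cts["H"] == 0L && cts["A"] <= 1L && cts["F"] <= 1L &&
      (cts["A"] == 0L || cts["F"] == 0L)) return("Tn")
  if (cts["N"] == 1L && cts["H"] >= 1L) return("core1")
  if (cts["N"] >= 2L && cts["H"] >= 1L) return("core2")
  "other"
}

.CORE_ORDER <- c("Tn", "core1", "core2", "other")

#' Decompose an unlocalized multi-site glycan mass into core-1 parts
#'
#' When site localization fails, a composition spanning several unresolved
#' sites can still be assigned when the HCD spectrum shows a 138/144 oxonium
#' ratio strictly under 1.2 (indicating core 1 structures) and no 407 m/z
#' di-HexNAc oxonium: a composition such as N2, H2N2 or H2N2A4 over two sites
#' is then split into equal single-site parts (two N1, H1N1 or H1N1A2).
#'
#' @param comp total \linkS4class{GlycanComposition}.
#' @param nUnresolvedSites number of unresolved candidate sites (>= 1).
#' @param has407 was an oxonium ion present at 407 m/z (two HexNAc in a
#'   single structure)?
#' @param ratio138144 intensity ratio I(138.055)/I(144.07).
#' @return list with elements \code{split} (logical) and \code{parts} (list of
#'   per-site compositions when split, otherwise NULL).
#' @export
decomposeMultisite <- function(comp, nUnresolvedSites, has407, ratio138144) {
  stopifnot(is(comp, "GlycanComposition"), nUnresolvedSites >= 1)
  keep <- list(split = FALSE, parts = NULL)
  if (nUnresolvedSites == 1L) return(keep)
  if (isTRUE(has407)) return(keep)
  if (!is.finite(ratio138144) || !(ratio138144 < 1.2)) return(keep)
  cts <- comp@counts
  if (any(cts %% nUnresolvedSites != 0L)) {
    warning("composition ", formatComposition(comp),
            " is not divisible by ", nUnresolvedSites, " sites; kept single")
    return(keep)
  }
  part <- new("GlycanComposition", counts = cts %/% as.integer(nUnresolvedSites))
  if (sum(part@counts) == 0L) return(keep)
  if (!classifyCore(part) %in% c("Tn", "core1")) return(keep)
  list(split = TRUE, parts = rep(list(part), nUnresolvedSites))
}

#' Bundled monosaccharide residue masses
#'
#' @return data.frame with columns symbol, name, formula, mass.
#' @export
monosaccharideMasses <- function() {
  path <- system.file("extdata", "monosaccharide_masses.csv",
                      package = "mucintools", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default O-glycan composition database
#'
#' Twelve common Tn, core 1 and core 2 compositions with masses and core
#' categories, bundled as a plain-text table.
#'
#' @return data.frame with columns composition, mass, category.
#' @export
defaultGlycanDatabase <- function() {
  path <- system.file("extdata", "default_glycans.csv",
                      package = "mucintools", mustWork = TRUE)
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  db$mass <- vapply(db$composition, compositionMass, numeric(1))
  db$category <- vapply(db$composition, classifyCore, character(1))
  db
}
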