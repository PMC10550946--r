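## Peptide-to-protein mapping, cleavage-site and glycosite accounting,
## structure/glycoform counting, enzyme overlap, and cleavage-motif windows.

#' Map a peptide onto a protein sequence
#'
#' @param protein protein sequence string.
#' @param peptide peptide sequence string.
#' @return integer vector of all 1-based exact start positions (possibly
#'   empty); an \code{ambiguous} attribute is TRUE when there is more than one
#'   occurrence.
#' @export
mapPeptide <- function(protein, peptide) {
  stopifnot(nzchar(protein), nzchar(peptide))
  hits <- gregexpr(peptide, protein, fixed = TRUE)[[1]]
  starts <- if (hits[1L] == -1L) integer() else as.integer(hits)
  attr(starts, "ambiguous") <- length(starts) > 1L
  starts
}

#' Derive cleavage events from mapped peptides
#'
#' A cleavage event is recorded at the 1-based index of the residue
#' immediately C-terminal to the scissile bond (the P1' residue). Each
#' peptide's N-terminal boundary is an event unless it is the protein
#' N-terminus; its C-terminal boundary is an event when the next residue
#' begins another observed peptide or is Ser/Thr. When trypsin was part of
#' the digestion, boundaries following Lys/Arg are excluded (they are tryptic,
#' not O-glycoprotease events).
#'
#' @param mapped data.frame with columns protein (id), start, end (1-based,
#'   inclusive peptide coordinates in the protein).
#' @param proteins named character vector of protein sequences.
#' @param enzyme enzyme id recorded on the events.
#' @param trypsin was trypsin used alongside the O-glycoprotease?
#' @return data.frame with columns protein, position, enzyme.
#' @export
cleavageSites <- function(mapped, proteins, enzyme = "enzyme",
                          trypsin = FALSE) {
  stopifnot(all(c("protein", "start", "end") %in% names(mapped)))
  rows <- list()
  addEvent <- function(prot, pos) {
    seqc <- proteins[[prot]]
    if (pos < 2L || pos > nchar(seqc)) return()
    if (trypsin && substr(seqc, pos - 1L, pos - 1L) %in% c("K", "R")) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      protein = prot, position = pos, enzyme = enzyme, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(mapped))) {
    prot <- mapped$protein[i]
    seqc <- proteins[[prot]]
    addEvent(prot, mapped$start[i])
    cterm <- mapped$end[i] + 1L
    if (cterm <= nchar(seqc)) {
      nextStartsPeptide <- any(mapped$protein == prot & mapped$start == cterm)
      nextIsST <- substr(seqc, cterm, cterm) %in% c("S", "T")
      if (nextStartsPeptide || nextIsST) addEvent(prot, cterm)
    }
  }
  if (!length(rows))
    return(data.frame(protein = character(), position = integer(),
                      enzyme = character(), stringsAsFactors = FALSE))
  unique(do.call(rbind, rows))
}

#' Localized and implied glycosites
#'
#' Localized glycosites come from validation; implied glycosites are Ser/Thr
#' residues at the P1' position of observed cleavage events that were not
#' themselves localized (cleavage was observed but the glycosite was not
#' localized by ETD evidence).
#'
#' @param localized data.frame with columns protein, site (localized sites).
#' @param events cleavage events from \code{\link{cleavageSites}}.
#' @param proteins named character vector of protein sequences (used to keep
#'   only Ser/Thr P1' residues).
#' @return list with data.frames \code{localized} and \code{implied} (no
#'   double counting).
#' @export
glycositeCounts <- function(localized, events, proteins) {
  loc <- unique(localized[, c("protein", "site")])
  p1p <- unique(events[, c("protein", "position")])
  isST <- vapply(seq_len(nrow(p1p)), function(i) {
    substr(proteins[[p1p$protein[i]]], p1p$position[i], p1p$position[i]) %in%
      c("S", "T")
  }, logical(1))
  p1p <- p1p[isST, , drop = FALSE]
  names(p1p) <- c("protein", "site")
  key <- function(df) paste(df$protein, df$site)
  implied <- p1p[!key(p1p) %in% key(loc), , drop = FALSE]
  rownames(implied) <- NULL
  list(localized = loc, implied = implied)
}

#' Count mapped glycan structures and unique glycoforms
#'
#' Mapped structures are distinct (protein, site, glycan) pairs over localized
#' site assignments (every O-glycan associated with each O-glycosite). Unique
#' glycoforms are distinct validated glycopeptides, identified by (peptide
#' sequence, glycan multiset, localization pattern); unlocalized variants of
#' the same composition collapse to one glycoform.
#'
#' @param validated data.frame with columns protein, peptide, glycanMultiset
#'   (canonical string of the sorted glycan multiset) and localization
#'   (string encoding of site:glycan pairs, "" when unlocalized), plus
#'   optional columns site and glycan for localized records.
#' @return list with \code{nMappedStructures} and \code{nUniqueGlycoforms}.
#' @export
countStructuresAndGlycoforms <- function(validated) {
  if (is.null(validated) || !nrow(validated))
    return(list(nMappedStructures = 0L, nUniqueGlycoforms = 0L))
  structures <- 0L
  if (all(c("site", "glycan") %in% names(validated))) {
    locRows <- validated[!is.na(validated$site) & nzchar(validated$glycan), ,
                         drop = FALSE]
    structures <- nrow(unique(locRows[, c("protein", "site", "glycan")]))
  }
  glycoforms <- nrow(unique(
    validated[, c("peptide", "glycanMultiset", "localization")]))
  list(nMappedStructures = structures, nUniqueGlycoforms = glycoforms)
}

#' Pairwise and triple overlaps between enzyme identifier sets
#'
#' @param sets named list (one element per enzyme) of character identifier
#'   vectors (glycosites, structures or glycoforms).
#' @return named numeric vector of set sizes, pairwise intersections and, for
#'   three or more enzymes, triple intersections, plus the union size.
#' @export
enzymeOverlap <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  out <- vapply(sets, length, numeric(1))
  nms <- names(sets)
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i < j)
      out[paste(nms[i], nms[j], sep = "&")] <-
        length(intersect(sets[[i]], sets[[j]]))
  }
  if (length(sets) >= 3L) {
    for (trip in utils::combn(seq_along(sets), 3L, simplify = FALSE))
      out[paste(nms[trip], collapse = "&")] <-
        length(Reduce(intersect, sets[trip]))
  }
  out["union"] <- length(Reduce(union, sets))
  out
}

#' Cleavage-motif windows and position frequency matrix
#'
#' Aligns +/- k residue windows around each cleavage event (positions
#' P-k..P1, P1'..Pk'), gap-padding at protein termini, and tallies column
#' frequencies over the 20 amino acids plus the gap character "-". When site
#' glycan assignments are supplied, per-position glycan tallies are reported
#' for P1 and P1'.
#'
#' @param proteins named character vector of protein sequences.
#' @param events cleavage events from \code{\link{cleavageSites}}.
#' @param k window half-width in residues (default 5).
#' @param siteGlycans optional data.frame with columns protein, site, glycan
#'   giving the glycan at glycosylated residues.
#' @return list with \code{windows} (character), \code{pfm} (21 x 2k matrix,
#'   columns P-k..Pk' each summing to 1) and \code{p1Glycans} /
#'   \code{p1primeGlycans} (named counts).
#' @export
motifWindows <- function(proteins, events, k = 5L, siteGlycans = NULL) {
  stopifnot(k >= 1L, nrow(events) >= 1L)
  colNames <- c(paste0("P", k:1), paste0("P", 1:k, "'"))
  windows <- character(nrow(events))
  mat <- matrix("-", nrow = nrow(events), ncol = 2L * k)
  for (i in seq_len(nrow(events))) {
    seqc <- proteins[[events$protein[i]]]
    pos <- events$position[i]
    idx <- (pos - k):(pos + k - 1L)     # P-k..P1 then P1'..Pk'
    chars <- ifelse(idx >= 1L & idx <= nchar(seqc),
                    substring(seqc, idx, idx), "-")
    mat[i, ] <- chars
    windows[i] <- paste(chars, collapse = "")
  }
  alphabet <- c(.AMINO_ACIDS, "-")
  pfm <- apply(mat, 2L, function(col) {
    tab <- table(factor(col, levels = alphabet))
    as.numeric(tab) / length(col)
  })
  rownames(pfm) <- alphabet
  colnames(pfm) <- colNames

  glycanTally <- function(offset) {
    if (is.null(siteGlycans)) return(NULL)
    key <- paste(siteGlycans$protein, siteGlycans$site)
    g <- vapply(seq_len(nrow(events)), function(i) {
      kk <- paste(events$protein[i], events$position[i] + offset)
      hit <- match(kk, key)
      if (is.na(hit)) "none" else siteGlycans$glycan[hit]
    }, character(1))
    table(g)
  }
  list(windows = windows, pfm = pfm,
       p1Glycans = glycanTally(-1L), p1primeGlycans = glycanTally(0L))
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
readProteinFasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>([^ ]+).*", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  stats::setNames(as.character(seqs), ids)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
writeProteinFasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(gsub("(.{60})", "\\1\n", seqs[[i]]), con)
  }
  invisible(path)
}
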