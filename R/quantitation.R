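## XIC area-under-curve abundance with mass-dependent isotope rules,
## charge-state summation, and category-first per-site aggregation.

#' Isotope peaks collected for a given neutral mass
#'
#' Only the 12C peak is used for anything under 1600 Da, the 13C is also
#' included up to 2400 Da (inclusive), and three isotopes are collected over
#' 2400 Da.
#'
#' @param neutralMass neutral monoisotopic mass in Da (> 0).
#' @return integer vector of isotope indices (0 = monoisotopic).
#' @export
isotopesForMass <- function(neutralMass) {
  if (!is.finite(neutralMass) || neutralMass <= 0)
    stop("neutral mass must be positive")
  if (neutralMass < 1600) 0L
  else if (neutralMass <= 2400) 0:1
  else 0:2
}

#' Area under the curve of a chromatographic trace
#'
#' Trapezoidal integral of intensity over retention time within a window.
#'
#' @param trace data.frame with ascending \code{rt} (minutes) and
#'   non-negative \code{intensity}.
#' @param rtWindow c(start, end) in minutes; defaults to the full trace.
#' @return area (intensity x min); 0 for an empty window.
#' @export
xicAuc <- function(trace, rtWindow = NULL) {
  stopifnot(all(c("rt", "intensity") %in% names(trace)))
  if (is.unsorted(trace$rt, strictly = TRUE))
    stop("retention times must be strictly increasing")
  if (is.null(rtWindow)) rtWindow <- range(trace$rt)
  if (rtWindow[1L] > rtWindow[2L]) stop("inverted retention-time window")
  sel <- trace$rt >= rtWindow[1L] & trace$rt <= rtWindow[2L]
  if (sum(sel) < 2L) return(0)
  pracma::trapz(trace$rt[sel], trace$intensity[sel])
}

#' Theoretical XIC channels for a glycoform
#'
#' Isotope channels at spacing 1.00335/z for the isotopes selected by
#' \code{\link{isotopesForMass}}, for each charge state.
#'
#' @param gp a \linkS4class{Glycopeptide}.
#' @param charges integer vector of observed charge states.
#' @return data.frame with columns mz, charge, isotope.
#' @export
glycoformChannels <- function(gp, charges) {
  M <- glycopeptideMass(gp)
  iso <- isotopesForMass(M)
  do.call(rbind, lapply(charges, function(z)
    data.frame(mz = (M + iso * .CONST$isotope + z * .CONST$proton) / z,
               charge = z, isotope = iso)))
}

#' Glycoform abundance from MS1 traces
#'
#' Sums XIC areas over all selected isotope channels and all observed charge
#' states.
#'
#' @param traces long-format data.frame with columns \code{mz} (channel m/z),
#'   \code{charge}, \code{rt}, \code{intensity}.
#' @param gp a \linkS4class{Glycopeptide}.
#' @param charges charge states to include.
#' @param tolPpm channel-matching tolerance in ppm (MS1 default 10).
#' @param rtWindow optional retention-time window (minutes).
#' @return total area; 0 with a warning when no channel is found.
#' @export
glycoformAbundance <- function(traces, gp, charges, tolPpm = 10,
                               rtWindow = NULL) {
  chan <- glycoformChannels(gp, charges)
  total <- 0
  found <- FALSE
  for (i in seq_len(nrow(chan))) {
    sel <- traces$charge == chan$charge[i] &
      abs(traces$mz - chan$mz[i]) / chan$mz[i] * 1e6 <= tolPpm
    if (!any(sel)) next
    found <- TRUE
    for (channelMz in unique(traces$mz[sel])) {
      tr <- traces[sel & traces$mz == channelMz, c("rt", "intensity")]
      tr <- tr[order(tr$rt), ]
      total <- total + xicAuc(tr, rtWindow)
    }
  }
  if (!found) warning("no XIC channels found for glycoform")
  total
}

#' Per-(protein, site, glycan) abundance table
#'
#' Sums the abundances of all peptides containing a given glycosite with a
#' given glycan, then normalizes to relative abundance within each site.
#'
#' @param records data.frame with columns protein, site, glycan (canonical
#'   composition string) and auc; one row per validated, localized glycoform
#'   occurrence.
#' @return data.frame with columns protein, site, glycan, auc,
#'   relativeAbundance (summing to 1 within each protein/site).
#' @export
siteGlycanTable <- function(records) {
  stopifnot(all(c("protein", "site", "glycan", "auc") %in% names(records)))
  agg <- stats::aggregate(auc ~ protein + site + glycan, data = records, FUN = sum)
  siteTotal <- stats::aggregate(auc ~ protein + site, data = agg, FUN = sum)
  names(siteTotal)[3L] <- "siteAuc"
  out <- merge(agg, siteTotal, by = c("protein", "site"))
  out$relativeAbundance <- out$auc / out$siteAuc
  out$siteAuc <- NULL
  out[order(out$protein, out$site, out$glycan), ]
}

#' Most abundant glycan per site, category first
#'
#' The winning core category (Tn, core 1, core 2, other) is chosen by summed
#' area, then the most abundant glycan within that category. Exact ties are
#' broken by the fixed category order Tn < core1 < core2 < other, then by
#' canonical composition string.
#'
#' @param table output of \code{\link{siteGlycanTable}}.
#' @return data.frame with columns protein, site, glycan, category.
#' @export
mostAbundantGlycanPerSite <- function(table) {
  stopifnot(nrow(table) > 0L)
  table$category <- vapply(table$glycan, classifyCore, character(1))
  keys <- unique(table[, c("protein", "site")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- table[table$protein == keys$protein[i] & table$site == keys$site[i], ]
    catSum <- tapply(sub$auc, sub$category, sum)
    catOrd <- match(names(catSum), .CORE_ORDER)
    best <- names(catSum)[order(-catSum, catOrd)][1L]
    inCat <- sub[sub$category == best, ]
    inCat <- inCat[order(-inCat$auc, inCat$glycan), ]
    data.frame(protein = keys$protein[i], site = keys$site[i],
               glycan = inCat$glycan[1L], category = best,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
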