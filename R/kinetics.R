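## One-phase exponential dissociation fitting for SPR sensorgrams.

#' Extract and re-zero a dissociation window from a sensorgram
#'
#' @param sensorgram data.frame with columns \code{time} (s) and
#'   \code{response} (RU).
#' @param window c(start, end) in seconds; time is re-zeroed at the window
#'   start.
#' @return data.frame with re-zeroed \code{time} and \code{response}.
#' @export
extractDissociation <- function(sensorgram, window) {
  stopifnot(all(c("time", "response") %in% names(sensorgram)),
            window[1L] < window[2L])
  sel <- sensorgram$time >= window[1L] & sensorgram$time <= window[2L]
  out <- sensorgram[sel, c("time", "response")]
  out$time <- out$time - window[1L]
  out[order(out$time), ]
}

#' Fit a one-phase exponential dissociation decay
#'
#' Nonlinear least squares of Y = (Y0 - NS) * exp(-K * X) + NS, where Y0 is
#' the binding at time zero, NS the nonspecific plateau at infinite time, and
#' K the dissociation rate constant koff (s^-1). Initialization: Y0 = first
#' response, NS = last response, K = 3 / time span; K is bounded positive.
#'
#' @param times dissociation times in seconds, ascending, re-zeroed at the
#'   dissociation start.
#' @param response response units.
#' @return list of class \code{decayFit} with K, Y0, NS, rss, converged and
#'   the model object (NULL on failure). Non-decaying data give
#'   \code{converged = FALSE} with diagnostics.
#' @export
fitDissociation <- function(times, response) {
  stopifnot(length(times) == length(response))
  if (length(times) < 4L) stop("need at least 4 points")
  if (is.unsorted(times)) stop("times must be ascending")
  span <- diff(range(times))
  start <- list(Y0 = response[1L], NS = response[length(response)],
                K = 3 / span)
  dat <- data.frame(X = times - times[1L], Y = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(Y ~ (Y0 - NS) * exp(-K * X) + NS, data = dat,
                      start = start, lower = c(Y0 = -Inf, NS = -Inf, K = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(K = NA_real_, Y0 = NA_real_, NS = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          diagnostics = "nonlinear fit failed", model = NULL),
                     class = "decayFit"))
  }
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  amplitude <- cf[["Y0"]] - cf[["NS"]]
  decaying <- amplitude > 0 && cf[["K"]] * span > 1e-3
  structure(list(K = cf[["K"]], Y0 = cf[["Y0"]], NS = cf[["NS"]], rss = rss,
                 converged = decaying,
                 diagnostics = if (decaying) "ok" else "no measurable decay",
                 model = fit),
            class = "decayFit")
}

#' @export
print.decayFit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("One-phase decay fit: koff = %.4g s^-1, Y0 = %.3g RU, NS = %.3g RU (rss %.3g)\n",
                x$K, x$Y0, x$NS, x$rss))
  else cat("One-phase decay fit: not converged (", x$diagnostics, ")\n")
  invisible(x)
}

#' Summarize koff over replicate fits
#'
#' Arithmetic mean and sample SD of K over converged fits; with a single
#' converged fit the SD is reported as 0 and flagged.
#'
#' @param fits list of \code{decayFit} objects.
#' @return list with \code{mean}, \code{sd}, \code{n} and
#'   \code{singleReplicate} flag.
#' @export
koffSummary <- function(fits) {
  ks <- vapply(fits, function(f) if (isTRUE(f$converged)) f$K else NA_real_,
               numeric(1))
  ks <- ks[!is.na(ks)]
  if (!length(ks)) stop("no converged fits")
  list(mean = mean(ks),
       sd = if (length(ks) > 1L) stats::sd(ks) else 0,
       n = length(ks), singleReplicate = length(ks) == 1L)
}
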