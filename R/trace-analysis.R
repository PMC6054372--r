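#' @include AllClasses.R wlc.R pulling.R
NULL

## Savitzky-Golay smoothing with graceful fallback for short traces.
.smoothForce <- function(force, window) {
  if (window < 3 || length(force) <= window) return(force)
  if (window %% 2 == 0) window <- window + 1
  p <- min(3, window - 2)
  as.numeric(signal::sgolayfilt(force, p = p, n = window))
}

#' Detect unfolding events in a force-extension trace
#'
#' Scans the smoothed force for local maxima followed by a force drop of at
#' least \code{minDrop} completing within a bounded extension window; peaks
#' below \code{minPeakForce} are ignored. Returns event positions and
#' rupture forces only; contour-length increments and classifications are
#' added by \code{\link{analyzeTrace}}.
#'
#' @param trace a \linkS4class{ForceExtensionTrace}.
#' @param minDrop minimum force drop that defines a rupture, pN.
#' @param minPeakForce minimum peak force for a reportable event, pN.
#' @param smoothWindow Savitzky-Golay window, samples (odd).
#' @param dropWindow extension span within which the drop must complete, nm.
#' @return data.frame(ruptureIndex, ruptureForce, extensionAtRupture); zero
#'   rows when nothing is detected.
#' @export
detectUnfoldingEvents <- function(trace, minDrop = 10, minPeakForce = 10,
                                  smoothWindow = 11, dropWindow = 50) {
  stopifnot(is(trace, "ForceExtensionTrace"))
  n <- length(trace@force)
  empty <- data.frame(ruptureIndex = integer(), ruptureForce = numeric(),
                      extensionAtRupture = numeric())
  if (n <= smoothWindow) return(empty)
  fs <- .smoothForce(trace@force, smoothWindow)
  if (diff(range(fs)) < minDrop) return(empty)
  ext <- trace@extension
  idx <- integer()
  start <- 1L
  repeat {
    seg <- fs[start:n]
    cm <- cummax(seg)
    drop <- cm - seg
    k <- which(drop >= minDrop & cm >= minPeakForce)
    if (!length(k)) break
    k <- k[1L]
    peak <- start - 1L + which.max(seg[seq_len(k)])
    fellAt <- start - 1L + k
    if (ext[fellAt] - ext[peak] <= dropWindow) idx <- c(idx, peak)
    ## advance past the whole drop: follow the descent to its valley, i.e.
    ## until the smoothed force has recovered by minDrop/2 from its running
    ## minimum, so one rupture yields one event
    seg2 <- fs[fellAt:n]
    rec <- which(seg2 - cummin(seg2) >= minDrop / 2)
    endIdx <- if (length(rec)) fellAt - 1L + rec[1L] else n
    start <- fellAt - 1L + which.min(fs[fellAt:endIdx])
    if (start >= n) break
  }
  ## smoothed peak value, capped at the observed maximum (the polynomial
  ## smoother can overshoot at the detachment cusp)
  data.frame(ruptureIndex = idx,
             ruptureForce = pmin(fs[idx], max(trace@force)),
             extensionAtRupture = ext[idx])
}

#' Fit a worm-like chain to one stretch segment
#'
#' Least-squares estimate of the contour length with the persistence length
#' held fixed, over samples whose force lies inside the fit band (by
#' default 5 pN up to 90% of the segment's peak force). Fixing the
#' persistence length stabilizes contour-length increments across
#' segments.
#'
#' @param trace a \linkS4class{ForceExtensionTrace}.
#' @param segmentBounds integer vector c(first, last) sample index.
#' @param fixedLp persistence length, nm.
#' @param temperature K.
#' @param forceBand c(min, max) force band in pN; an NA maximum means
#'   0.9 times the segment's peak force.
#' @param minSamples minimum in-band samples required for a fit.
#' @return list(lc, residual, nUsed, skipped, reason): \code{lc} is the
#'   fitted contour length (nm, larger than the maximum extension in the
#'   segment) and \code{residual} the root-mean-square force residual (pN);
#'   degenerate segments come back with \code{skipped = TRUE} and a reason.
#' @export
fitSegmentWLC <- function(trace, segmentBounds, fixedLp = 0.4,
                          temperature = 298, forceBand = c(5, NA),
                          minSamples = 10) {
  stopifnot(is(trace, "ForceExtensionTrace"), length(segmentBounds) == 2L)
  i0 <- max(1L, as.integer(segmentBounds[1]))
  i1 <- min(length(trace@force), as.integer(segmentBounds[2]))
  skip <- function(reason)
    list(lc = NA_real_, residual = NA_real_, nUsed = 0L,
         skipped = TRUE, reason = reason)
  if (i1 - i0 + 1L < minSamples) return(skip("too short"))
  f <- trace@force[i0:i1]
  x <- trace@extension[i0:i1]
  fmax <- if (is.na(forceBand[2])) 0.9 * max(f) else forceBand[2]
  use <- f >= forceBand[1] & f <= fmax & x > 0
  if (sum(use) < minSamples) return(skip("too few samples in force band"))
  f <- f[use]; x <- x[use]
  xmax <- max(x)
  ss <- function(lc) {
    p <- WLCParams(fixedLp, lc, temperature)
    sum((f - wlcForce(x, p))^2)
  }
  opt <- stats::optimize(ss, interval = c(xmax * (1 + 1e-9), xmax * 6),
                         tol = 1e-7 * xmax)
  list(lc = opt$minimum, residual = sqrt(opt$objective / length(f)),
       nUsed = length(f), skipped = FALSE, reason = "")
}

#' Classify unfolding events
#'
#' Applies the single-molecule fingerprint logic: the last detected event is
#' the detachment; events whose contour-length increment falls in the I27
#' fingerprint window and whose rupture force exceeds the fingerprint force
#' threshold are fingerprints; the remaining internal events are talin
#' unfoldings. Events without a measurable increment are left unknown.
#'
#' @param events data.frame with at least ruptureForce and deltaLc columns.
#' @param fingerprintDeltaLc c(min, max) fingerprint increment window, nm.
#' @param fingerprintMinForce minimum fingerprint rupture force, pN.
#' @return the events data.frame with a classification column
#'   (fingerprint, talin, detachment, unknown).
#' @export
classifyEvents <- function(events, fingerprintDeltaLc = c(24, 32),
                           fingerprintMinForce = 120) {
  if (nrow(events) == 0L) {
    events$classification <- character(0)
    return(events)
  }
  cls <- rep("unknown", nrow(events))
  known <- !is.na(events$deltaLc)
  fp <- known &
    events$deltaLc >= fingerprintDeltaLc[1] &
    events$deltaLc <= fingerprintDeltaLc[2] &
    events$ruptureForce > fingerprintMinForce
  cls[known] <- "talin"
  cls[fp] <- "fingerprint"
  cls[nrow(events)] <- "detachment"
  events$classification <- cls
  events
}

#' Analyse one force-extension trace
#'
#' The full per-trace pipeline: event detection, per-segment worm-like-chain
#' fits with fixed persistence length, contour-length increments as the
#' difference of consecutive fitted contour lengths, event classification,
#' fingerprint-based acceptance, and the per-trace unfolding length (sum of
#' talin-classified increments). Traces lacking the required number of
#' fingerprint events, or lacking any talin event, are rejected with a
#' reason.
#'
#' @param trace a \linkS4class{ForceExtensionTrace}.
#' @param minDrop,minPeakForce,smoothWindow,dropWindow event-detection
#'   settings, see \code{\link{detectUnfoldingEvents}}.
#' @param fixedLp,temperature,forceBand,minSamples segment-fit settings, see
#'   \code{\link{fitSegmentWLC}}.
#' @param fingerprintDeltaLc,fingerprintMinForce classification windows, see
#'   \code{\link{classifyEvents}}.
#' @param minFingerprints fingerprint events required to accept a trace as
#'   single-molecule evidence.
#' @return A \linkS4class{TraceResult}.
#' @export
analyzeTrace <- function(trace, minDrop = 10, minPeakForce = 10,
                         smoothWindow = 11, dropWindow = 50,
                         fixedLp = 0.4, temperature = 298,
                         forceBand = c(5, NA), minSamples = 10,
                         fingerprintDeltaLc = c(24, 32),
                         fingerprintMinForce = 120, minFingerprints = 2) {
  ev <- detectUnfoldingEvents(trace, minDrop, minPeakForce, smoothWindow,
                              dropWindow)
  reject <- function(reason, events) {
    ev2 <- if (nrow(events)) classifyEvents(events, fingerprintDeltaLc,
                                            fingerprintMinForce) else {
      events$deltaLc <- numeric(0)
      events$classification <- character(0)
      events
    }
    new("TraceResult", events = ev2, unfoldingLength = NA_real_,
        accepted = FALSE, reason = reason)
  }
  if (nrow(ev) == 0L) {
    ev$lcBefore <- ev$lcAfter <- ev$deltaLc <- numeric(0)
    return(reject("no events detected", ev))
  }
  fs <- .smoothForce(trace@force, smoothWindow)
  m <- nrow(ev)
  ## segment i runs from the valley after event i-1 to the peak of event i
  segStart <- integer(m)
  segStart[1] <- 1L
  if (m > 1) {
    for (i in 2:m) {
      between <- (ev$ruptureIndex[i - 1] + 1L):ev$ruptureIndex[i]
      segStart[i] <- between[which.min(fs[between])]
    }
  }
  lc <- vapply(seq_len(m), function(i) {
    fit <- fitSegmentWLC(trace, c(segStart[i], ev$ruptureIndex[i]),
                         fixedLp, temperature, forceBand, minSamples)
    if (fit$skipped) NA_real_ else fit$lc
  }, numeric(1))
  ev$lcBefore <- lc
  ev$lcAfter <- c(lc[-1], NA_real_)
  ev$deltaLc <- ev$lcAfter - ev$lcBefore
  ev <- classifyEvents(ev, fingerprintDeltaLc, fingerprintMinForce)
  nfp <- sum(ev$classification == "fingerprint")
  if (nfp < minFingerprints)
    return(reject(sprintf(
      "only %d fingerprint events (need %d) - not single-molecule evidence",
      nfp, minFingerprints), ev[setdiff(names(ev), "classification")]))
  talin <- ev$classification == "talin" & !is.na(ev$deltaLc) & ev$deltaLc > 0
  if (!any(talin))
    return(reject("no talin events",
                  ev[setdiff(names(ev), "classification")]))
  new("TraceResult", events = ev,
      unfoldingLength = sum(ev$deltaLc[talin]),
      accepted = TRUE, reason = "")
}

#' Analyse a dataset of traces
#'
#' @param traces list of \linkS4class{ForceExtensionTrace}.
#' @param ... passed to \code{\link{analyzeTrace}}.
#' @return List of \linkS4class{TraceResult}.
#' @export
analyzeDataset <- function(traces, ...) {
  lapply(traces, analyzeTrace, ...)
}

#' Per-trace unfolding lengths of the accepted traces in a cohort
#'
#' @param results list of \linkS4class{TraceResult}.
#' @return Numeric vector of unfolding lengths (nm), one per accepted trace.
#' @export
cohortUnfoldingLengths <- function(results) {
  keep <- vapply(results, isAccepted, logical(1))
  vapply(results[keep], unfoldingLength, numeric(1))
}

#' Gaussian fit to a histogram of values
#'
#' Bins the data at the requested width and fits a single Gaussian
#' (amplitude, mean, sd) to the bin counts by least squares, as applied to
#' unfolding-length and unfolding-force histograms. Sample moments are
#' reported alongside as a cross-check. Zero-spread input is returned as a
#' degenerate fit rather than an error.
#'
#' @param values numeric data (>= 3 finite values).
#' @param binWidth histogram bin width in data units; NULL (the default)
#'   chooses a resolving width by the Freedman-Diaconis rule, so the fit
#'   stays identifiable whatever the cohort spread. Pass an explicit width
#'   (e.g. 5 nm for lengths, 2 pN for forces) to mirror figure-style
#'   histograms.
#' @return A \linkS4class{GaussianFit}.
#' @export
fitGaussianHistogram <- function(values, binWidth = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 finite values for a histogram fit")
  m <- mean(values)
  s <- stats::sd(values)
  if (is.null(binWidth)) {
    binWidth <- 2 * stats::IQR(values) / n^(1 / 3)
    if (binWidth <= 0) binWidth <- 3.5 * s / n^(1 / 3)
    if (binWidth <= 0) binWidth <- 1
  }
  if (s == 0 || diff(range(values)) < .Machine$double.eps * abs(m))
    return(new("GaussianFit", mean = m, sd = 0, amplitude = n, n = n,
               sampleMean = m, sampleSd = 0, degenerate = TRUE))
  breaks <- seq(min(values) - binWidth, max(values) + binWidth,
                by = binWidth)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  ## model the counts as amplitude times the Gaussian mass in each bin
  ## (midpoint evaluation biases the centre when sd < bin width)
  dat <- data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                    cnt = h$counts)
  fit <- tryCatch({
    fm <- minpack.lm::nlsLM(
      cnt ~ A * (pnorm(hi, mu, sg) - pnorm(lo, mu, sg)), data = dat,
      start = list(A = n, mu = m, sg = s),
      lower = c(0, min(values) - binWidth, binWidth / 50),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fm)
    mu <- unname(cf["mu"]); sg <- abs(unname(cf["sg"]))
    A <- unname(cf["A"])
    list(mean = mu, sd = sg,
         amplitude = A * (stats::pnorm(binWidth / 2, 0, sg) -
                          stats::pnorm(-binWidth / 2, 0, sg)))
  }, error = function(e) list(mean = m, sd = s, amplitude = max(dat$cnt)))
  new("GaussianFit", mean = fit$mean, sd = fit$sd,
      amplitude = fit$amplitude, n = n, sampleMean = m, sampleSd = s,
      degenerate = FALSE)
}
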