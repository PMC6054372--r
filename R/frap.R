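#' @include AllClasses.R
NULL

#' Standard FRAP acquisition schedule
#'
#' The study protocol: five prebleach TIRF frames at 5 s intervals, then
#' post-bleach frames every 5 s for 100 s, with t = 0 at the first
#' post-bleach frame.
#'
#' @param nPrebleach prebleach frames.
#' @param interval frame interval, s.
#' @param postDuration post-bleach duration, s.
#' @return list(times, nPrebleach) with prebleach times negative.
#' @export
frapSchedule <- function(nPrebleach = 5, interval = 5, postDuration = 100) {
  list(times = c(-rev(seq_len(nPrebleach)) * interval,
                 seq(0, postDuration, by = interval)),
       nPrebleach = nPrebleach)
}

#' Simulate a FRAP recovery curve
#'
#' Exponential-recovery truth \eqn{n(t) = floor + (plateau - floor)(1 -
#' e^{-t/\tau})} for the post-bleach samples and 1 for the prebleach
#' samples, plus i.i.d. Gaussian noise, optionally mapped onto a raw
#' intensity scale. The generating parameters are stored as ground truth.
#'
#' @param floor normalized intensity at t = 0+ (0 <= floor <= plateau <= 1).
#' @param plateau normalized recovery asymptote.
#' @param tau recovery time constant, s (> 0).
#' @param noiseSd additive Gaussian noise sd (normalized units).
#' @param schedule acquisition schedule from \code{\link{frapSchedule}}.
#' @param seed RNG seed.
#' @param scale,background map the normalized curve onto raw intensities
#'   \code{background + scale * n(t)}; with the defaults (1, 0) the curve
#'   is returned on the normalized scale.
#' @return A \linkS4class{FRAPCurve}.
#' @export
simulateFrapCurve <- function(floor, plateau, tau, noiseSd = 0,
                              schedule = frapSchedule(), seed = NULL,
                              scale = 1, background = 0) {
  if (floor < 0 || plateau < floor || plateau > 1)
    stop("parameters must satisfy 0 <= floor <= plateau <= 1")
  if (tau <= 0) stop("tau must be > 0")
  times <- schedule$times
  npre <- schedule$nPrebleach
  post <- times >= 0
  n <- ifelse(post, floor + (plateau - floor) * (1 - exp(-times / tau)), 1)
  withSeed(seed, {
    if (noiseSd > 0) n <- n + stats::rnorm(length(n), 0, noiseSd)
    FRAPCurve(times, background + scale * n, nPrebleach = npre,
              background = background,
              normalized = (scale == 1 && background == 0),
              truth = list(floor = floor, plateau = plateau, tau = tau))
  })
}

#' Normalize a FRAP curve between prebleach intensity and background
#'
#' Maps the fluorescent signal so the prebleach mean is 1 and the
#' background is 0: \eqn{n(t) = (I(t) - b) / (\bar I_{pre} - b)}.
#' Idempotent on already-normalized curves.
#'
#' @param raw a \linkS4class{FRAPCurve}.
#' @param background background intensity, a.u.; defaults to the curve's
#'   recorded background. Must lie below the prebleach mean.
#' @return A normalized \linkS4class{FRAPCurve}.
#' @export
normalizeFrap <- function(raw, background = raw@background) {
  stopifnot(is(raw, "FRAPCurve"))
  pre <- mean(raw@intensities[seq_len(raw@nPrebleach)])
  if (background >= pre)
    stop("background must be below the prebleach mean intensity")
  FRAPCurve(raw@times, (raw@intensities - background) / (pre - background),
            nPrebleach = raw@nPrebleach, background = 0,
            normalized = TRUE, truth = raw@truth)
}

## Profiled least squares for the single-exponential recovery: at fixed tau
## the model is linear in (floor, plateau - floor), so the nonlinear search
## is 1-D over log(tau). Deterministic, no convergence failures.
.profiledSS <- function(logTau, t, y) {
  g <- 1 - exp(-t / exp(logTau))
  X <- cbind(1, g)
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Fit a single-exponential FRAP recovery
#'
#' Least-squares fit of \eqn{n(t) = floor + (plateau - floor)(1 -
#' e^{-t/\tau})} to the post-bleach samples of a normalized curve. The
#' search is profiled: at fixed \eqn{\tau} the remaining parameters are
#' linear, so a 1-D minimization over \eqn{\log\tau} suffices. The immobile
#' fraction is \eqn{1 - (plateau - floor)/(1 - floor)}, clamped to [0, 1].
#'
#' @param curve a normalized \linkS4class{FRAPCurve} with >= 8 post-bleach
#'   samples.
#' @return A \linkS4class{FRAPFit}.
#' @export
fitRecovery <- function(curve) {
  stopifnot(is(curve, "FRAPCurve"))
  if (!curve@normalized)
    stop("curve must be normalized first (see normalizeFrap)")
  post <- curve@times >= 0
  t <- curve@times[post]
  y <- curve@intensities[post]
  if (length(t) < 8)
    stop("need at least 8 post-bleach samples")
  tmax <- max(t[t > 0])
  opt <- stats::optimize(.profiledSS, t = t, y = y,
                         interval = log(c(tmax / 1e4, tmax * 100)),
                         tol = 1e-10)
  tau <- exp(opt$minimum)
  g <- 1 - exp(-t / tau)
  cf <- stats::lm.fit(cbind(1, g), y)$coefficients
  fl <- unname(cf[1]); pl <- unname(cf[1] + cf[2])
  denom <- 1 - fl
  imm <- if (abs(denom) < 1e-12) 1 else 1 - (pl - fl) / denom
  imm <- min(max(imm, 0), 1)
  new("FRAPFit", floor = fl, plateau = pl, tau = tau, immobile = imm,
      residualSS = opt$objective, nPoints = length(t),
      converged = is.finite(opt$objective))
}

#' Extra-sum-of-squares F test between two FRAP conditions
#'
#' Nested-model comparison on the pooled post-bleach points: the null model
#' fits one recovery-parameter set to both groups together
#' (\eqn{SS_{shared}}), the alternative fits each group separately
#' (\eqn{SS_{sep} = SS_A + SS_B}), and
#' \deqn{F = \frac{(SS_{shared} - SS_{sep})/(df_{shared} - df_{sep})}
#'            {SS_{sep}/df_{sep}}}
#' is referred to the F distribution with those degrees of freedom.
#'
#' @param groupA,groupB lists of normalized \linkS4class{FRAPCurve}.
#' @return An \linkS4class{FTestResult}.
#' @export
extraSSFTest <- function(groupA, groupB) {
  pool <- function(curves) {
    stopifnot(length(curves) >= 1)
    ts <- ys <- numeric(0)
    for (cv in curves) {
      stopifnot(is(cv, "FRAPCurve"))
      if (!cv@normalized) stop("all curves must be normalized")
      post <- cv@times >= 0
      ts <- c(ts, cv@times[post]); ys <- c(ys, cv@intensities[post])
    }
    list(t = ts, y = ys)
  }
  a <- pool(groupA); b <- pool(groupB)
  fitSS <- function(t, y) {
    tmax <- max(t[t > 0])
    stats::optimize(.profiledSS, t = t, y = y,
                    interval = log(c(tmax / 1e4, tmax * 100)),
                    tol = 1e-10)$objective
  }
  ssA <- fitSS(a$t, a$y)
  ssB <- fitSS(b$t, b$y)
  ssShared <- fitSS(c(a$t, b$t), c(a$y, b$y))
  N <- length(a$t) + length(b$t)
  dfSep <- N - 6          # two 3-parameter fits
  dfShared <- N - 3
  if (dfSep <= 0) stop("too few points for separate fits (df <= 0)")
  ssSep <- ssA + ssB
  f <- ((ssShared - ssSep) / (dfShared - dfSep)) / (ssSep / dfSep)
  f <- max(f, 0)
  new("FTestResult", fStatistic = f, dfNum = dfShared - dfSep,
      dfDen = dfSep,
      pValue = stats::pf(f, dfShared - dfSep, dfSep, lower.tail = FALSE))
}

## ---------------------------------------------------------------------------
## Stain-ratio quantification
## ---------------------------------------------------------------------------

#' Per-cell intensity ratio of two aligned stain images
#'
#' Background-corrected ratio of mean masked intensities, as used for the
#' pMLC-2 / total MLC-2 quantification: for each cell mask,
#' \code{(mean num - bgNum) / (mean den - bgDen)}. Cells whose
#' background-corrected denominator is not positive are flagged and
#' excluded (ratio NA).
#'
#' @param numeratorImage,denominatorImage aligned numeric matrices.
#' @param cellMasks a logical matrix or a list of logical matrices (one
#'   per cell), each the size of the images and non-empty.
#' @param backgroundNumerator,backgroundDenominator per-channel background
#'   levels, a.u.
#' @return data.frame(cell, ratio, flagged).
#' @export
intensityRatio <- function(numeratorImage, denominatorImage, cellMasks,
                           backgroundNumerator = 0,
                           backgroundDenominator = 0) {
  stopifnot(all(dim(numeratorImage) == dim(denominatorImage)))
  if (is.matrix(cellMasks) || !is.list(cellMasks))
    cellMasks <- list(cellMasks)
  out <- lapply(seq_along(cellMasks), function(i) {
    m <- cellMasks[[i]]
    stopifnot(all(dim(m) == dim(numeratorImage)))
    if (!any(m)) stop("cell mask ", i, " is empty")
    num <- mean(numeratorImage[m]) - backgroundNumerator
    den <- mean(denominatorImage[m]) - backgroundDenominator
    if (den <= 0)
      data.frame(cell = i, ratio = NA_real_, flagged = TRUE)
    else
      data.frame(cell = i, ratio = num / den, flagged = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a pair of stain images with known per-cell ratios
#'
#' Renders disk-shaped "cells" with uniform denominator intensity and
#' numerator intensity equal to the configured true ratio times the
#' denominator, over a constant background, plus Gaussian noise. Returns
#' the two channels, the per-cell masks and the truth.
#'
#' @param trueRatios numeric vector of per-cell ratios.
#' @param imageSize image edge, px.
#' @param cellRadius disk radius, px.
#' @param denominatorLevel denominator intensity inside a cell, a.u.
#' @param background per-channel background, a.u.
#' @param noiseSd Gaussian noise sd, a.u.
#' @param seed RNG seed.
#' @return list(numerator, denominator, masks, trueRatios).
#' @export
simulateStainImages <- function(trueRatios, imageSize = 96,
                                cellRadius = 10, denominatorLevel = 500,
                                background = 50, noiseSd = 0, seed = 1) {
  nc <- length(trueRatios)
  perRow <- ceiling(sqrt(nc))
  pitch <- floor(imageSize / perRow)
  if (pitch < 2 * cellRadius + 4)
    stop("cells do not fit: enlarge imageSize or shrink cellRadius")
  num <- den <- matrix(background, imageSize, imageSize)
  masks <- vector("list", nc)
  xs <- seq_len(imageSize); ys <- seq_len(imageSize)
  for (i in seq_len(nc)) {
    cx <- ((i - 1) %% perRow + 0.5) * pitch
    cy <- ((i - 1) %/% perRow + 0.5) * pitch
    m <- outer(ys, xs, function(y, x) (x - cx)^2 + (y - cy)^2 <=
                 cellRadius^2)
    masks[[i]] <- m
    den[m] <- background + denominatorLevel
    num[m] <- background + trueRatios[i] * denominatorLevel
  }
  withSeed(seed, {
    if (noiseSd > 0) {
      num <- num + matrix(stats::rnorm(length(num), 0, noiseSd),
                          imageSize, imageSize)
      den <- den + matrix(stats::rnorm(length(den), 0, noiseSd),
                          imageSize, imageSize)
    }
    list(numerator = num, denominator = den, masks = masks,
         trueRatios = trueRatios)
  })
}
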