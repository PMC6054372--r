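#' @include AllClasses.R wlc.R construct.R
NULL

#' Bell unfolding rate under force
#'
#' Force-accelerated barrier crossing, \eqn{k(F) = k_0 \exp(F \Delta x /
#' k_B T)}.
#'
#' @param force force in pN (vectorized).
#' @param k0 zero-force unfolding rate, 1/s.
#' @param dx distance to the transition state, nm.
#' @param temperature K.
#' @return Rate in 1/s.
#' @export
bellRate <- function(force, k0, dx, temperature = 298) {
  k0 * exp(force * dx / thermalEnergy(temperature))
}

#' Most probable rupture force under a constant loading rate
#'
#' Closed-form mode of the Bell-Evans rupture-force distribution,
#' \eqn{F^* = (k_B T/\Delta x)\,\ln\!\left(r \Delta x / (k_0 k_B T)\right)},
#' floored at zero. Used as the analytic cross-check for the stochastic
#' pulling simulator.
#'
#' @param k0,dx Bell parameters (1/s, nm).
#' @param loadingRate pN/s.
#' @param temperature K.
#' @return Modal rupture force in pN.
#' @export
bellEvansModalForce <- function(k0, dx, loadingRate, temperature = 298) {
  kT <- thermalEnergy(temperature)
  pmax(0, (kT / dx) * log(loadingRate * dx / (k0 * kT)))
}

#' Bell-Evans rupture-force distribution function
#'
#' Analytic CDF of the rupture force under a constant loading rate
#' \eqn{r}: \eqn{P(F) = 1 - \exp\{-(k_0 k_B T / (r \Delta x))
#' [\exp(F \Delta x / k_B T) - 1]\}}.
#'
#' @param force pN (vectorized).
#' @param k0,dx Bell parameters.
#' @param loadingRate pN/s.
#' @param temperature K.
#' @return Cumulative probability.
#' @export
bellEvansRuptureCDF <- function(force, k0, dx, loadingRate,
                                temperature = 298) {
  kT <- thermalEnergy(temperature)
  1 - exp(-(k0 * kT / (loadingRate * dx)) *
            (exp(force * dx / kT) - 1))
}

#' Cantilever stiffness from thermal fluctuations
#'
#' Equipartition calibration: the spring constant of a cantilever follows
#' from the variance of its thermal deflection, \eqn{k = c\, k_B T /
#' \langle d^2 \rangle}, with a dimensionless geometry factor \eqn{c}
#' correcting for the optical-lever readout of the fundamental mode.
#'
#' @param deflectionVariance thermal deflection variance, nm^2 (> 0).
#' @param temperature K.
#' @param geometryFactor dimensionless correction (default 1).
#' @return Stiffness in pN/nm.
#' @examples
#' equipartitionStiffness(0.4114, 298)  # 10 pN/nm
#' @export
equipartitionStiffness <- function(deflectionVariance, temperature = 298,
                                   geometryFactor = 1) {
  if (any(deflectionVariance <= 0))
    stop("deflectionVariance must be > 0 (nm^2)")
  geometryFactor * thermalEnergy(temperature) / deflectionVariance
}

## ---------------------------------------------------------------------------
## Timestep accuracy guard
## ---------------------------------------------------------------------------

## Effective loading rate of a constant-velocity protocol near rupture:
## velocity times the series stiffness of cantilever and WLC, evaluated
## self-consistently at the modal rupture force with the all-folded contour
## (the stiffest, hence most conservative, configuration).
.effectiveLoadingRate <- function(construct, protocol, k0, dx) {
  if (protocol@mode == "force_ramp") return(protocol@loadingRate)
  params <- WLCParams(protocol@persistenceLength, foldedContour(construct),
                      protocol@temperature)
  Fstar <- 10
  r <- protocol@cantileverStiffness * protocol@velocity
  for (i in 1:10) {
    x <- wlcExtension(Fstar, params)
    kw <- .wlcStiffness(x, params)
    kser <- 1 / (1 / protocol@cantileverStiffness + 1 / kw)
    r <- protocol@velocity * kser
    Fstar <- max(bellEvansModalForce(k0, dx, r, protocol@temperature), 1e-3)
  }
  r
}

## Refuse timesteps that cannot resolve rupture forces: at the modal
## rupture force the per-step hazard equals (r dx / kBT) dt, so the guard
## k(F*) dt <= 0.1 bounds the hazard growth per step. Domains whose modal
## force is zero (spontaneous unfolding) pose no resolution problem and are
## exempt.
.checkTimestep <- function(construct, protocol) {
  kT <- thermalEnergy(protocol@temperature)
  for (d in domains(construct)) {
    if (d@clamped) next
    r <- .effectiveLoadingRate(construct, protocol, d@k0, d@dx)
    Fstar <- bellEvansModalForce(d@k0, d@dx, r, protocol@temperature)
    if (Fstar > 0 &&
        bellRate(Fstar, d@k0, d@dx, protocol@temperature) *
          protocol@timestep > 0.1)
      stop(sprintf(
        paste0("timestep %.3g s too large: k(F)*dt = %.3g > 0.1 at the ",
               "typical rupture force of domain '%s'; reduce the timestep"),
        protocol@timestep,
        bellRate(Fstar, d@k0, d@dx, protocol@temperature) *
          protocol@timestep, d@name))
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Simulation
## ---------------------------------------------------------------------------

#' Simulate one force-extension pulling cycle
#'
#' Constant-velocity mode solves, at every timestep, the force balance
#' between the cantilever spring and the worm-like chain of the
#' currently-unfolded contour; each folded, unclamped domain then unfolds
#' with probability \eqn{1 - \exp(-k(F)\,dt)} under Bell kinetics, which
#' instantaneously adds its contour-length release to the tether. Clamped
#' domains never unfold. The tether detaches when the force reaches the
#' protocol's detachment force, after which a short zero-force baseline is
#' appended. Gaussian force noise is added last; the returned trace carries
#' the ground-truth event table.
#'
#' Force-ramp mode applies a deterministic force ramp directly (force
#' control), with the same Bernoulli unfolding rule.
#'
#' @param construct a \linkS4class{PolyproteinConstruct}.
#' @param protocol a \linkS4class{PullingProtocol}.
#' @param seed integer seed; the simulation is reproducible given
#'   (seed, construct, protocol).
#' @param baselineSamples samples of free-cantilever baseline appended
#'   after detachment (constant-velocity mode).
#' @return A \linkS4class{ForceExtensionTrace}.
#' @examples
#' tr <- simulateTrace(talinR7R8Construct(),
#'                     PullingProtocol(forceNoiseSd = 5), seed = 1)
#' groundTruth(tr)
#' @export
simulateTrace <- function(construct, protocol, seed,
                          baselineSamples = 120) {
  stopifnot(is(construct, "PolyproteinConstruct"),
            is(protocol, "PullingProtocol"))
  .checkTimestep(construct, protocol)
  withSeed(seed, {
    if (protocol@mode == "constant_velocity")
      .simulateCV(construct, protocol, baselineSamples)
    else
      .simulateRamp(construct, protocol)
  })
}

.simulateCV <- function(construct, protocol, baselineSamples) {
  doms <- domains(construct)
  nd <- length(doms)
  k0v <- vapply(doms, function(d) d@k0, numeric(1))
  dxv <- vapply(doms, function(d) d@dx, numeric(1))
  relv <- vapply(doms, releasedLength, numeric(1))
  clampv <- vapply(doms, function(d) d@clamped, logical(1))
  namev <- vapply(doms, function(d) d@name, character(1))
  folded <- rep(TRUE, nd)

  kc <- protocol@cantileverStiffness
  dt <- protocol@timestep
  v <- protocol@velocity
  kT <- thermalEnergy(protocol@temperature)
  Lp <- protocol@persistenceLength
  Lc <- foldedContour(construct)

  nmax <- 4e6
  cap <- 4096L
  time <- piezo <- force <- ext <- numeric(cap)
  n <- 0L
  gt <- list()
  x <- 0
  i <- 0L
  repeat {
    i <- i + 1L
    if (i > nmax) stop("simulation failed to reach detachment")
    t <- i * dt
    z <- v * t
    ## force balance: kc (z - x) = F_wlc(x; Lc), Newton from previous x
    ## with bisection safeguard
    lo <- 0
    hi <- min(z, Lc * (1 - 1e-12))
    if (hi <= 0) {
      x <- 0
      F <- 0
    } else {
      x <- min(max(x, lo), hi)
      for (it in 1:80) {
        tt <- x / Lc
        Fw <- (kT / Lp) * (0.25 / (1 - tt)^2 - 0.25 + tt)
        g <- kc * (z - x) - Fw
        if (abs(g) < 1e-10) break
        if (g > 0) lo <- x else hi <- x
        dg <- -kc - (kT / Lp) * (0.5 / (1 - tt)^3 + 1) / Lc
        xn <- x - g / dg
        if (!is.finite(xn) || xn <= lo || xn >= hi) xn <- (lo + hi) / 2
        x <- xn
      }
      F <- kc * (z - x)
    }
    if (n == cap) {
      cap <- cap * 2L
      length(time) <- cap; length(piezo) <- cap
      length(force) <- cap; length(ext) <- cap
    }
    n <- n + 1L
    time[n] <- t; piezo[n] <- z; force[n] <- F; ext[n] <- x

    if (F >= protocol@detachForce) break

    ## one uniform draw per domain per step keeps the RNG stream aligned
    ## between otherwise-identical constructs (e.g. WT vs clamped)
    u <- stats::runif(nd)
    eps <- stats::rnorm(1)   # reserved noise draw, applied below
    if (protocol@forceNoiseSd > 0)
      force[n] <- force[n] + protocol@forceNoiseSd * eps
    hot <- folded & !clampv
    if (any(hot)) {
      p <- 1 - exp(-bellRate(F, k0v, dxv, protocol@temperature) * dt)
      fired <- hot & (u < p)
      if (any(fired)) {
        for (j in which(fired)) {
          gt[[length(gt) + 1L]] <- data.frame(
            domain = namev[j], index = n, time = t, force = F,
            deltaLc = relv[j], stringsAsFactors = FALSE)
        }
        folded[fired] <- FALSE
        Lc <- Lc + sum(relv[fired])
      }
    }
  }
  ## free cantilever after detachment: zero force, tip follows the piezo
  if (baselineSamples > 0) {
    tb <- time[n] + dt * seq_len(baselineSamples)
    zb <- v * tb
    fb <- if (protocol@forceNoiseSd > 0)
      stats::rnorm(baselineSamples, 0, protocol@forceNoiseSd) else
      numeric(baselineSamples)
    time <- c(time[seq_len(n)], tb)
    piezo <- c(piezo[seq_len(n)], zb)
    force <- c(force[seq_len(n)], fb)
    ext <- c(ext[seq_len(n)], zb)
  } else {
    time <- time[seq_len(n)]; piezo <- piezo[seq_len(n)]
    force <- force[seq_len(n)]; ext <- ext[seq_len(n)]
  }
  gtdf <- if (length(gt)) do.call(rbind, gt) else .emptyGroundTruth()
  new("ForceExtensionTrace", time = time, piezo = piezo, force = force,
      extension = ext, cantileverStiffness = kc, groundTruth = gtdf)
}

.simulateRamp <- function(construct, protocol) {
  doms <- domains(construct)
  dt <- protocol@timestep
  r <- protocol@loadingRate
  kT <- thermalEnergy(protocol@temperature)
  nstep <- ceiling(protocol@detachForce / (r * dt))
  tgrid <- dt * seq_len(nstep)
  Fgrid <- r * tgrid
  relv <- vapply(doms, releasedLength, numeric(1))
  gt <- list()
  ruptureStep <- rep(NA_integer_, length(doms))
  for (j in seq_along(doms)) {
    d <- doms[[j]]
    if (d@clamped) { stats::runif(1); next }   # keep stream aligned
    p <- 1 - exp(-bellRate(Fgrid, d@k0, d@dx, protocol@temperature) * dt)
    logS <- cumsum(log1p(-pmin(p, 1 - 1e-15)))
    u <- stats::runif(1)
    hit <- which(logS < log(u))
    if (length(hit)) {
      k <- hit[1L]
      ruptureStep[j] <- k
      gt[[length(gt) + 1L]] <- data.frame(
        domain = d@name, index = k, time = tgrid[k], force = Fgrid[k],
        deltaLc = relv[j], stringsAsFactors = FALSE)
    }
  }
  ## truncate shortly after the last rupture (or keep the full ramp if a
  ## domain never unfolded before the detachment force)
  last <- if (all(is.na(ruptureStep)) ||
              any(is.na(ruptureStep) &
                  !vapply(doms, function(d) d@clamped, logical(1))))
    nstep else min(nstep, max(ruptureStep, na.rm = TRUE) + 20L)
  tgrid <- tgrid[seq_len(last)]
  Fgrid <- Fgrid[seq_len(last)]
  ## extension under force control: piecewise per unfolding state
  Lc <- foldedContour(construct)
  bounds <- sort(unique(c(0L, ruptureStep[!is.na(ruptureStep)], last)))
  ext <- numeric(last)
  gtdf <- if (length(gt)) do.call(rbind, gt) else .emptyGroundTruth()
  if (nrow(gtdf) > 1L) gtdf <- gtdf[order(gtdf$index), , drop = FALSE]
  evIdx <- c(gtdf$index, last + 1L)
  start <- 1L
  for (s in seq_along(evIdx)) {
    stop_ <- min(evIdx[s], last)
    if (start <= stop_) {
      params <- WLCParams(protocol@persistenceLength, Lc,
                          protocol@temperature)
      idx <- start:stop_
      ext[idx] <- wlcExtension(Fgrid[idx], params)
    }
    if (s <= nrow(gtdf)) Lc <- Lc + gtdf$deltaLc[s]
    start <- stop_ + 1L
    if (start > last) break
  }
  Fnoisy <- if (protocol@forceNoiseSd > 0)
    Fgrid + stats::rnorm(last, 0, protocol@forceNoiseSd) else Fgrid
  piezo <- ext + Fgrid / protocol@cantileverStiffness
  new("ForceExtensionTrace", time = tgrid, piezo = piezo, force = Fnoisy,
      extension = ext, cantileverStiffness = protocol@cantileverStiffness,
      groundTruth = gtdf)
}

#' Simulate a dataset of pulling traces
#'
#' Runs \code{\link{simulateTrace}} \code{n} times with per-trace seeds
#' derived deterministically from the master seed, so a dataset is
#' reproducible given (seed, construct, protocol).
#'
#' @param construct a \linkS4class{PolyproteinConstruct}.
#' @param protocol a \linkS4class{PullingProtocol}.
#' @param n number of traces (>= 1); the study recorded 82 wild-type and
#'   56 clamp traces.
#' @param seed master seed.
#' @param baselineSamples passed to \code{\link{simulateTrace}}.
#' @return List of \linkS4class{ForceExtensionTrace}.
#' @export
simulateDataset <- function(construct, protocol, n, seed,
                            baselineSamples = 120) {
  if (n < 1) stop("n must be >= 1")
  seeds <- deriveSeeds(seed, n)
  lapply(seeds, function(s)
    simulateTrace(construct, protocol, seed = s,
                  baselineSamples = baselineSamples))
}
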