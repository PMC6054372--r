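#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Polymer elasticity
## ---------------------------------------------------------------------------

#' Worm-like-chain parameter set
#'
#' Bundles the persistence length \eqn{L_p}, contour length \eqn{L_c} and
#' absolute temperature used by the Marko-Siggia interpolation. The thermal
#' energy \eqn{k_B T} is derived, never stored.
#'
#' @slot persistenceLength persistence length in nm (> 0)
#' @slot contourLength contour length in nm (> persistence length)
#' @slot temperature absolute temperature in K (> 0)
#' @export
setClass("WLCParams",
  representation(
    persistenceLength = "numeric",
    contourLength     = "numeric",
    temperature       = "numeric"
  )
)

setValidity("WLCParams", function(object) {
  msg <- character()
  if (length(object@persistenceLength) != 1L || object@persistenceLength <= 0)
    msg <- c(msg, "persistenceLength must be a single positive value (nm)")
  if (length(object@contourLength) != 1L || object@contourLength <= 0)
    msg <- c(msg, "contourLength must be a single positive value (nm)")
  if (length(object@temperature) != 1L || object@temperature <= 0)
    msg <- c(msg, "temperature must be a single positive value (K)")
  if (length(msg) == 0L &&
      object@persistenceLength >= object@contourLength)
    msg <- c(msg, "persistenceLength must be smaller than contourLength")
  if (length(msg)) msg else TRUE
})

#' Construct a WLCParams object
#'
#' @param persistenceLength persistence length in nm; the 0.4 nm default is
#'   the standard value for an unfolded polypeptide chain.
#' @param contourLength contour length in nm.
#' @param temperature absolute temperature in K (default 298, room
#'   temperature).
#' @return A \linkS4class{WLCParams} object.
#' @examples
#' p <- WLCParams(contourLength = 100)
#' thermalEnergy(p@temperature)
#' @export
WLCParams <- function(persistenceLength = 0.4, contourLength,
                      temperature = 298) {
  new("WLCParams",
      persistenceLength = as.numeric(persistenceLength),
      contourLength     = as.numeric(contourLength),
      temperature       = as.numeric(temperature))
}

setMethod("show", "WLCParams", function(object) {
  cat(sprintf(
    "WLCParams: Lp = %.3g nm, Lc = %.4g nm, T = %.4g K (kBT = %.4g pN nm)\n",
    object@persistenceLength, object@contourLength, object@temperature,
    thermalEnergy(object@temperature)))
})

## ---------------------------------------------------------------------------
## Polyprotein bookkeeping
## ---------------------------------------------------------------------------

#' A foldable domain within a polyprotein
#'
#' Each domain carries the contour length it releases on unfolding
#' (\code{deltaLc}), Bell kinetics (zero-force unfolding rate \code{k0},
#' distance to the transition state \code{dx}), its folded end-to-end size
#' (which contributes to the tether contour while folded), and an optional
#' disulphide-clamp flag. A clamped domain never unfolds and therefore
#' releases zero length.
#'
#' @slot name domain label
#' @slot nResidues number of residues spanned by the unfoldable segment
#' @slot deltaLc contour length released on unfolding, nm (> 0)
#' @slot k0 unfolding rate at zero force, 1/s
#' @slot dx distance to the unfolding transition state, nm
#' @slot foldedSize folded end-to-end size passed through to the tether, nm
#' @slot clamped whether a disulphide clamp prevents unfolding
#' @slot clampSpan residues bridged by the clamp (0 when unclamped)
#' @export
setClass("FoldableDomain",
  representation(
    name       = "character",
    nResidues  = "numeric",
    deltaLc    = "numeric",
    k0         = "numeric",
    dx         = "numeric",
    foldedSize = "numeric",
    clamped    = "logical",
    clampSpan  = "numeric"
  )
)

setValidity("FoldableDomain", function(object) {
  msg <- character()
  if (object@deltaLc <= 0)
    msg <- c(msg, "deltaLc must be > 0 (nm)")
  if (object@k0 <= 0 || object@dx <= 0)
    msg <- c(msg, "Bell parameters k0 and dx must be > 0")
  if (object@foldedSize < 0)
    msg <- c(msg, "foldedSize must be >= 0")
  if (object@clampSpan > object@nResidues)
    msg <- c(msg, "clampSpan cannot exceed nResidues")
  if (object@clamped && object@clampSpan <= 0)
    msg <- c(msg, "a clamped domain must record a positive clampSpan")
  if (length(msg)) msg else TRUE
})

#' @rdname FoldableDomain-class
#' @param name,nResidues,deltaLc,k0,dx,foldedSize,clamped,clampSpan see slots
#' @return A \linkS4class{FoldableDomain}.
#' @export
FoldableDomain <- function(name, nResidues, deltaLc, k0, dx,
                           foldedSize = 4.5, clamped = FALSE,
                           clampSpan = if (clamped) nResidues else 0) {
  new("FoldableDomain",
      name = as.character(name), nResidues = as.numeric(nResidues),
      deltaLc = as.numeric(deltaLc), k0 = as.numeric(k0),
      dx = as.numeric(dx), foldedSize = as.numeric(foldedSize),
      clamped = isTRUE(clamped), clampSpan = as.numeric(clampSpan))
}

## Contour length a domain actually releases when it unfolds.
#' Length released by a domain on unfolding (zero when clamped)
#' @param domain a \linkS4class{FoldableDomain}
#' @return release in nm
#' @export
releasedLength <- function(domain) {
  if (domain@clamped) 0 else domain@deltaLc
}

setMethod("show", "FoldableDomain", function(object) {
  cat(sprintf(
    "FoldableDomain '%s': %d aa, dLc = %.4g nm%s, k0 = %.3g /s, dx = %.3g nm\n",
    object@name, as.integer(object@nResidues), object@deltaLc,
    if (object@clamped) " (clamped: releases 0 nm)" else "",
    object@k0, object@dx))
})

#' An ordered polyprotein construct
#'
#' Ordered foldable domains plus the contour of the always-unfolded handle
#' (HaloTag, linkers). The tether contour at any time is the handle plus the
#' folded end-to-end sizes of all domains plus the releases of the domains
#' unfolded so far; unfolding a domain increases the contour by exactly its
#' \code{deltaLc}.
#'
#' @slot domains ordered list of \linkS4class{FoldableDomain}
#' @slot handleContour contour of always-unfolded linkers/tags, nm
#' @export
setClass("PolyproteinConstruct",
  representation(domains = "list", handleContour = "numeric"))

setValidity("PolyproteinConstruct", function(object) {
  msg <- character()
  if (!all(vapply(object@domains, is, logical(1), "FoldableDomain")))
    msg <- c(msg, "domains must all be FoldableDomain objects")
  if (length(object@handleContour) != 1L || object@handleContour < 0)
    msg <- c(msg, "handleContour must be a single value >= 0 (nm)")
  nm <- vapply(object@domains, function(d) d@name, character(1))
  if (anyDuplicated(nm))
    msg <- c(msg, "domain names must be unique")
  if (length(msg)) msg else TRUE
})

#' @rdname PolyproteinConstruct-class
#' @param domains ordered list of \linkS4class{FoldableDomain}
#' @param handleContour handle contour in nm
#' @return A \linkS4class{PolyproteinConstruct}.
#' @export
PolyproteinConstruct <- function(domains, handleContour = 30) {
  new("PolyproteinConstruct", domains = domains,
      handleContour = as.numeric(handleContour))
}

#' @describeIn PolyproteinConstruct-class ordered domain list
#' @param x a PolyproteinConstruct
#' @export
setMethod("domains", "PolyproteinConstruct", function(x) x@domains)

#' @describeIn PolyproteinConstruct-class handle contour (nm)
#' @export
setMethod("handleContour", "PolyproteinConstruct", function(x) x@handleContour)

#' @describeIn PolyproteinConstruct-class tether contour with every domain
#'   folded: handle plus folded end-to-end sizes (nm)
#' @export
setMethod("foldedContour", "PolyproteinConstruct", function(x) {
  x@handleContour + sum(vapply(x@domains, function(d) d@foldedSize, numeric(1)))
})

#' @describeIn PolyproteinConstruct-class total contour the construct can
#'   release, i.e. the sum of deltaLc over unclamped domains (nm)
#' @export
setMethod("releasableContour", "PolyproteinConstruct", function(x) {
  sum(vapply(x@domains, releasedLength, numeric(1)))
})

setMethod("show", "PolyproteinConstruct", function(object) {
  cat(sprintf("PolyproteinConstruct: %d domains, handle %.3g nm\n",
              length(object@domains), object@handleContour))
  for (d in object@domains) show(d)
  cat(sprintf("  folded contour %.4g nm, releasable %.4g nm\n",
              foldedContour(object), releasableContour(object)))
})

## ---------------------------------------------------------------------------
## Pulling simulation
## ---------------------------------------------------------------------------

#' Pulling protocol for the smAFM simulator
#'
#' Constant-velocity retraction (the study protocol: 400 nm/s with a 4-10
#' pN/nm cantilever) or a force ramp at a fixed loading rate.
#'
#' @slot mode "constant_velocity" or "force_ramp"
#' @slot velocity retraction velocity, nm/s
#' @slot cantileverStiffness cantilever spring constant, pN/nm
#' @slot loadingRate loading rate for ramp mode, pN/s
#' @slot timestep integration step, s
#' @slot forceNoiseSd additive Gaussian force noise, pN
#' @slot detachForce force at which the tether detaches, pN
#' @slot persistenceLength unfolded-chain persistence length, nm
#' @slot temperature K
#' @export
setClass("PullingProtocol",
  representation(
    mode                = "character",
    velocity            = "numeric",
    cantileverStiffness = "numeric",
    loadingRate         = "numeric",
    timestep            = "numeric",
    forceNoiseSd        = "numeric",
    detachForce         = "numeric",
    persistenceLength   = "numeric",
    temperature         = "numeric"
  )
)

setValidity("PullingProtocol", function(object) {
  msg <- character()
  if (!object@mode %in% c("constant_velocity", "force_ramp"))
    msg <- c(msg, "mode must be 'constant_velocity' or 'force_ramp'")
  if (object@mode == "constant_velocity" && object@velocity <= 0)
    msg <- c(msg, "velocity must be > 0 in constant_velocity mode")
  if (object@mode == "force_ramp" && object@loadingRate <= 0)
    msg <- c(msg, "loadingRate must be > 0 in force_ramp mode")
  if (object@timestep <= 0)
    msg <- c(msg, "timestep must be > 0")
  if (object@forceNoiseSd < 0)
    msg <- c(msg, "forceNoiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname PullingProtocol-class
#' @param mode,velocity,cantileverStiffness,loadingRate,timestep,forceNoiseSd,detachForce,persistenceLength,temperature
#'   see slots
#' @return A \linkS4class{PullingProtocol}.
#' @export
PullingProtocol <- function(mode = c("constant_velocity", "force_ramp"),
                            velocity = 400, cantileverStiffness = 7,
                            loadingRate = 100, timestep = 2.5e-4,
                            forceNoiseSd = 0, detachForce = 280,
                            persistenceLength = 0.4, temperature = 298) {
  mode <- match.arg(mode)
  new("PullingProtocol", mode = mode, velocity = as.numeric(velocity),
      cantileverStiffness = as.numeric(cantileverStiffness),
      loadingRate = as.numeric(loadingRate), timestep = as.numeric(timestep),
      forceNoiseSd = as.numeric(forceNoiseSd),
      detachForce = as.numeric(detachForce),
      persistenceLength = as.numeric(persistenceLength),
      temperature = as.numeric(temperature))
}

setMethod("show", "PullingProtocol", function(object) {
  if (object@mode == "constant_velocity")
    cat(sprintf(
      "PullingProtocol: constant velocity %.4g nm/s, cantilever %.3g pN/nm\n",
      object@velocity, object@cantileverStiffness))
  else
    cat(sprintf("PullingProtocol: force ramp %.4g pN/s\n", object@loadingRate))
  cat(sprintf("  dt = %.3g s, force noise sd = %.3g pN, detach at %.4g pN\n",
              object@timestep, object@forceNoiseSd, object@detachForce))
})

#' A force-extension trace
#'
#' Time, piezo position, force and tip extension series of one pulling
#' cycle. Simulated traces carry a ground-truth event table (domain name,
#' rupture time/index/force, released contour) used by recovery tests; the
#' invariant extension = piezo - force/k holds for the pre-noise force.
#'
#' @slot time s, strictly increasing
#' @slot piezo piezo position, nm
#' @slot force measured (possibly noisy) force, pN
#' @slot extension tip extension, nm (pre-noise)
#' @slot cantileverStiffness pN/nm (NA for ramp-mode or imported traces)
#' @slot groundTruth data.frame(domain, index, time, force, deltaLc); zero
#'   rows for imported traces
#' @export
setClass("ForceExtensionTrace",
  representation(
    time = "numeric", piezo = "numeric", force = "numeric",
    extension = "numeric", cantileverStiffness = "numeric",
    groundTruth = "data.frame"
  )
)

setValidity("ForceExtensionTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@piezo) != n || length(object@force) != n ||
      length(object@extension) != n)
    msg <- c(msg, "time, piezo, force, extension must have equal length")
  if (n > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  gt <- object@groundTruth
  need <- c("domain", "index", "time", "force", "deltaLc")
  if (!all(need %in% names(gt)))
    msg <- c(msg, sprintf("groundTruth must have columns %s",
                          paste(need, collapse = ", ")))
  else if (nrow(gt) > 1L && is.unsorted(gt$time))
    msg <- c(msg, "groundTruth events must be time-ordered")
  if (length(msg)) msg else TRUE
})

.emptyGroundTruth <- function() {
  data.frame(domain = character(), index = integer(), time = numeric(),
             force = numeric(), deltaLc = numeric(),
             stringsAsFactors = FALSE)
}

#' @describeIn ForceExtensionTrace-class ground-truth event table
#' @param x a ForceExtensionTrace
#' @export
setMethod("groundTruth", "ForceExtensionTrace", function(x) x@groundTruth)

setMethod("show", "ForceExtensionTrace", function(object) {
  cat(sprintf(
    "ForceExtensionTrace: %d samples, %.3g s, max force %.4g pN, %d events\n",
    length(object@time), max(object@time), max(object@force),
    nrow(object@groundTruth)))
})

setMethod("length", "ForceExtensionTrace", function(x) length(x@time))

## ---------------------------------------------------------------------------
## Trace analysis results
## ---------------------------------------------------------------------------

#' Per-trace analysis result
#'
#' Detected unfolding events with fitted contour-length increments and
#' classifications, plus the per-trace unfolding length (the sum of
#' talin-classified increments). A trace is only accepted when the
#' single-molecule fingerprint criterion is met; rejected traces carry a
#' reason and no unfolding length.
#'
#' @slot events data.frame(ruptureIndex, ruptureForce, extensionAtRupture,
#'   lcBefore, lcAfter, deltaLc, classification)
#' @slot unfoldingLength nm; NA when not accepted
#' @slot accepted logical
#' @slot reason rejection reason ("" when accepted)
#' @export
setClass("TraceResult",
  representation(events = "data.frame", unfoldingLength = "numeric",
                 accepted = "logical", reason = "character"))

setValidity("TraceResult", function(object) {
  if (!object@accepted && !is.na(object@unfoldingLength))
    return("a rejected trace must not report an unfolding length")
  if (object@accepted && (is.na(object@unfoldingLength) ||
                          object@unfoldingLength < 0))
    return("an accepted trace must report a non-negative unfolding length")
  TRUE
})

#' @describeIn TraceResult-class detected event table
#' @param x a TraceResult
#' @export
setMethod("events", "TraceResult", function(x) x@events)

#' @describeIn TraceResult-class per-trace unfolding length (nm)
#' @export
setMethod("unfoldingLength", "TraceResult", function(x) x@unfoldingLength)

#' @describeIn TraceResult-class was the trace accepted?
#' @export
setMethod("isAccepted", "TraceResult", function(x) x@accepted)

setMethod("show", "TraceResult", function(object) {
  if (object@accepted)
    cat(sprintf("TraceResult: accepted, %d events, unfolding length %.4g nm\n",
                nrow(object@events), object@unfoldingLength))
  else
    cat(sprintf("TraceResult: rejected (%s), %d events\n",
                object@reason, nrow(object@events)))
})

#' Gaussian fit to a histogram
#'
#' Least-squares single-Gaussian fit to binned data, as applied to
#' unfolding-length and unfolding-force histograms. Sample moments are kept
#' alongside as a cross-check; degenerate inputs (all values identical) are
#' flagged rather than fitted.
#'
#' @slot mean,sd fitted Gaussian centre and width (data units)
#' @slot amplitude fitted peak height, counts
#' @slot n number of observations
#' @slot sampleMean,sampleSd sample moments
#' @slot degenerate flag for zero-spread input
#' @export
setClass("GaussianFit",
  representation(mean = "numeric", sd = "numeric", amplitude = "numeric",
                 n = "numeric", sampleMean = "numeric", sampleSd = "numeric",
                 degenerate = "logical"))

setValidity("GaussianFit", function(object) {
  if (object@sd < 0) return("sd must be >= 0")
  TRUE
})

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf("GaussianFit: mean %.4g, sd %.4g (n = %d%s)\n",
              object@mean, object@sd, as.integer(object@n),
              if (object@degenerate) ", degenerate" else ""))
})

## ---------------------------------------------------------------------------
## Micropillar TFM
## ---------------------------------------------------------------------------

#' Micropillar array geometry and optics
#'
#' @slot nx,ny number of pillars along x (columns) and y (rows)
#' @slot spacing centre-to-centre pillar spacing, um
#' @slot stiffness pillar bending stiffness, nN/um
#' @slot psfSigma Gaussian point-spread sigma of a pillar image, px
#' @slot pixelSize um per pixel
#' @slot amplitude,background spot peak and background intensity, a.u.
#' @export
setClass("PillarGrid",
  representation(nx = "numeric", ny = "numeric", spacing = "numeric",
                 stiffness = "numeric", psfSigma = "numeric",
                 pixelSize = "numeric", amplitude = "numeric",
                 background = "numeric"))

setValidity("PillarGrid", function(object) {
  msg <- character()
  if (object@stiffness <= 0) msg <- c(msg, "stiffness must be > 0 (nN/um)")
  if (object@spacing <= 4 * object@psfSigma * object@pixelSize)
    msg <- c(msg, "spacing must exceed 4 * psfSigma * pixelSize (spots overlap)")
  if (object@pixelSize <= 0 || object@psfSigma <= 0)
    msg <- c(msg, "pixelSize and psfSigma must be > 0")
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname PillarGrid-class
#' @param nx,ny,spacing,stiffness,psfSigma,pixelSize,amplitude,background
#'   see slots; defaults are a 12 x 12 array at 2 um pitch, 15 nN/um
#'   pillars imaged at 0.16 um/px.
#' @return A \linkS4class{PillarGrid}.
#' @export
PillarGrid <- function(nx = 12, ny = 12, spacing = 2, stiffness = 15,
                       psfSigma = 1.3, pixelSize = 0.16,
                       amplitude = 1000, background = 100) {
  new("PillarGrid", nx = as.numeric(nx), ny = as.numeric(ny),
      spacing = as.numeric(spacing), stiffness = as.numeric(stiffness),
      psfSigma = as.numeric(psfSigma), pixelSize = as.numeric(pixelSize),
      amplitude = as.numeric(amplitude), background = as.numeric(background))
}

## spacing in pixels
.spacingPx <- function(grid) grid@spacing / grid@pixelSize

setMethod("show", "PillarGrid", function(object) {
  cat(sprintf(
    "PillarGrid: %d x %d pillars, %.3g um pitch (%.3g px), k = %.3g nN/um\n",
    as.integer(object@nx), as.integer(object@ny), object@spacing,
    .spacingPx(object), object@stiffness))
})

#' Synthetic pillar movie with ground truth
#'
#' Image stack plus the true subpixel positions used to render it, the
#' nominal grid nodes, the applied stage drift and the cell mask (pillars
#' under the synthetic cell).
#'
#' @slot frames numeric array [rows, cols, frames]
#' @slot truth array [pillar, (x, y), frame] of true positions, px
#' @slot nodes matrix [pillar, (x, y)] of nominal grid nodes, px
#' @slot drift matrix [frame, (x, y)], px
#' @slot cellMask logical per pillar
#' @slot grid the generating \linkS4class{PillarGrid}
#' @export
setClass("PillarMovie",
  representation(frames = "array", truth = "array", nodes = "matrix",
                 drift = "matrix", cellMask = "logical", grid = "PillarGrid"))

setValidity("PillarMovie", function(object) {
  nf <- dim(object@frames)[3]
  np <- nrow(object@nodes)
  if (dim(object@truth)[1] != np || dim(object@truth)[3] != nf)
    return("truth array must be [pillars, 2, frames]")
  if (nrow(object@drift) != nf)
    return("drift must have one row per frame")
  if (length(object@cellMask) != np)
    return("cellMask must have one entry per pillar")
  TRUE
})

setMethod("show", "PillarMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("PillarMovie: %d x %d px, %d frames, %d pillars (%d in cell)\n",
              d[1], d[2], d[3], nrow(object@nodes), sum(object@cellMask)))
})

#' Linked pillar tracks
#'
#' Per-pillar subpixel positions across frames, with interpolation flags for
#' frames where localization failed, reference (cell-free) flags, and a
#' record of whether stage drift has been removed.
#'
#' @slot positions array [pillar, (x, y), frame], px
#' @slot nodes matrix [pillar, (x, y)] nominal nodes, px
#' @slot isReference logical per pillar
#' @slot interpolated logical matrix [pillar, frame]
#' @slot driftCorrected logical
#' @slot grid \linkS4class{PillarGrid}
#' @export
setClass("PillarTrackSet",
  representation(positions = "array", nodes = "matrix",
                 isReference = "logical", interpolated = "matrix",
                 driftCorrected = "logical", grid = "PillarGrid"))

setValidity("PillarTrackSet", function(object) {
  np <- nrow(object@nodes)
  if (dim(object@positions)[1] != np)
    return("positions must have one row per pillar")
  if (length(object@isReference) != np)
    return("isReference must have one entry per pillar")
  if (!all(dim(object@interpolated) ==
           c(np, dim(object@positions)[3])))
    return("interpolated must be [pillars, frames]")
  TRUE
})

setMethod("show", "PillarTrackSet", function(object) {
  cat(sprintf(
    "PillarTrackSet: %d pillars x %d frames (%d reference)%s\n",
    dim(object@positions)[1], dim(object@positions)[3],
    sum(object@isReference),
    if (object@driftCorrected) ", drift-corrected" else ""))
})

#' Pillar displacement and force map
#'
#' Per-pillar displacement (nm) and force (nN) vectors per frame, with
#' displacements measured against frame 0 (the zero-force reference). Force
#' is exactly stiffness times displacement, componentwise; the peak force per
#' pillar is the maximum magnitude over frames and the cell-average force is
#' the mean of peak forces over cell-mask pillars.
#'
#' @slot displacements array [pillar, (x, y), frame], nm
#' @slot forces array [pillar, (x, y), frame], nN
#' @slot peakForce numeric per pillar, nN
#' @slot cellMask logical per pillar
#' @slot cellMean mean of peak forces over the cell mask, nN
#' @slot stiffness nN/um
#' @export
setClass("ForceMap",
  representation(displacements = "array", forces = "array",
                 peakForce = "numeric", cellMask = "logical",
                 cellMean = "numeric", stiffness = "numeric"))

#' @describeIn ForceMap-class per-pillar peak forces (nN)
#' @param x a ForceMap
#' @export
setMethod("peakForces", "ForceMap", function(x) x@peakForce)

#' @describeIn ForceMap-class mean of peak forces over cell pillars (nN)
#' @export
setMethod("cellMeanForce", "ForceMap", function(x) x@cellMean)

setMethod("show", "ForceMap", function(object) {
  cat(sprintf(
    "ForceMap: %d pillars x %d frames, cell-average peak force %.4g nN\n",
    dim(object@forces)[1], dim(object@forces)[3], object@cellMean))
})

## ---------------------------------------------------------------------------
## FRAP
## ---------------------------------------------------------------------------

#' A FRAP intensity time series
#'
#' Prebleach samples (the study protocol: five TIRF frames at 5 s spacing)
#' followed by post-bleach recovery (5 s intervals for 100 s), with t = 0 at
#' the first post-bleach frame. Normalization maps the prebleach mean to 1
#' and the background to 0. Simulated curves carry their generating truth.
#'
#' @slot times s; prebleach times are negative, t = 0 is the first
#'   post-bleach frame
#' @slot intensities a.u. (or normalized units)
#' @slot nPrebleach number of prebleach samples (>= 2)
#' @slot background a.u.
#' @slot normalized logical
#' @slot truth list(floor, plateau, tau) for simulated curves, else empty
#' @export
setClass("FRAPCurve",
  representation(times = "numeric", intensities = "numeric",
                 nPrebleach = "numeric", background = "numeric",
                 normalized = "logical", truth = "list"))

setValidity("FRAPCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@intensities))
    msg <- c(msg, "times and intensities must have equal length")
  if (object@nPrebleach < 2)
    msg <- c(msg, "at least 2 prebleach samples are required")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (object@normalized) {
    pre <- object@intensities[seq_len(object@nPrebleach)]
    if (abs(mean(pre) - 1) > 0.2)
      msg <- c(msg, "normalized curve must have prebleach mean near 1")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname FRAPCurve-class
#' @param times,intensities,nPrebleach,background,normalized,truth see slots
#' @return A \linkS4class{FRAPCurve}.
#' @export
FRAPCurve <- function(times, intensities, nPrebleach = 5, background = 0,
                      normalized = FALSE, truth = list()) {
  new("FRAPCurve", times = as.numeric(times),
      intensities = as.numeric(intensities),
      nPrebleach = as.numeric(nPrebleach),
      background = as.numeric(background),
      normalized = isTRUE(normalized), truth = truth)
}

#' @describeIn FRAPCurve-class has the curve been normalized?
#' @param x a FRAPCurve
#' @export
setMethod("isNormalized", "FRAPCurve", function(x) x@normalized)

setMethod("show", "FRAPCurve", function(object) {
  cat(sprintf(
    "FRAPCurve: %d samples (%d prebleach), %s\n",
    length(object@times), as.integer(object@nPrebleach),
    if (object@normalized) "normalized" else "raw intensities"))
})

#' Fitted FRAP recovery
#'
#' Single-exponential recovery n(t) = floor + (plateau - floor) *
#' (1 - exp(-t/tau)) fitted to a normalized curve. The immobile fraction is
#' 1 - (plateau - floor) / (1 - floor): the proportion of the bleached
#' population that does not exchange within the observation window.
#'
#' @slot floor normalized intensity immediately after bleaching
#' @slot plateau normalized recovery asymptote
#' @slot tau recovery time constant, s
#' @slot immobile immobile fraction in [0, 1]
#' @slot residualSS residual sum of squares of the fit
#' @slot nPoints post-bleach samples used
#' @slot converged logical
#' @export
setClass("FRAPFit",
  representation(floor = "numeric", plateau = "numeric", tau = "numeric",
                 immobile = "numeric", residualSS = "numeric",
                 nPoints = "numeric", converged = "logical"))

setValidity("FRAPFit", function(object) {
  if (object@immobile < -1e-9 || object@immobile > 1 + 1e-9)
    return("immobile fraction must lie in [0, 1]")
  if (object@tau <= 0) return("tau must be > 0")
  TRUE
})

#' @describeIn FRAPFit-class the fitted immobile fraction
#' @param x a FRAPFit
#' @export
setMethod("immobileFraction", "FRAPFit", function(x) x@immobile)

setMethod("show", "FRAPFit", function(object) {
  cat(sprintf(
    "FRAPFit: floor %.3g, plateau %.3g, tau %.4g s, immobile fraction %.3g\n",
    object@floor, object@plateau, object@tau, object@immobile))
})

#' Extra-sum-of-squares F test result
#'
#' @slot fStatistic F statistic (>= 0 up to rounding)
#' @slot dfNum,dfDen numerator/denominator degrees of freedom
#' @slot pValue upper-tail p value
#' @export
setClass("FTestResult",
  representation(fStatistic = "numeric", dfNum = "numeric",
                 dfDen = "numeric", pValue = "numeric"))

setValidity("FTestResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must lie in [0, 1]")
  TRUE
})

setMethod("show", "FTestResult", function(object) {
  cat(sprintf("Extra-sum-of-squares F test: F(%d, %d) = %.4g, p = %.3g\n",
              as.integer(object@dfNum), as.integer(object@dfDen),
              object@fStatistic, object@pValue))
})
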