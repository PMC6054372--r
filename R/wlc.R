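#' @include AllClasses.R
NULL

#' Worm-like-chain force at a given extension
#'
#' Marko-Siggia interpolation for the entropic restoring force of a
#' worm-like chain,
#' \deqn{F(x) = \frac{k_B T}{L_p}\left[\frac{1}{4(1 - x/L_c)^2} -
#'   \frac{1}{4} + \frac{x}{L_c}\right],}
#' strictly increasing in the extension and divergent as \eqn{x \to L_c}.
#' This is the force model applied to every stretch segment of a
#' force-extension trace.
#'
#' @param extension end-to-end extension in nm; vectorized. Must satisfy
#'   0 <= extension < contour length.
#' @param params a \linkS4class{WLCParams} object.
#' @return Force in pN (same length as \code{extension}).
#' @examples
#' wlcForce(50, WLCParams(0.4, 100, 298))  # 12.86 pN
#' @seealso \code{\link{wlcExtension}} for the numerical inverse.
#' @export
wlcForce <- function(extension, params) {
  stopifnot(is(params, "WLCParams"))
  if (any(!is.finite(extension)))
    stop("extension must be finite")
  if (any(extension < 0))
    stop("extension must be >= 0")
  if (any(extension >= params@contourLength))
    stop("extension must be smaller than the contour length")
  kT <- thermalEnergy(params@temperature)
  t <- extension / params@contourLength
  (kT / params@persistenceLength) * (0.25 / (1 - t)^2 - 0.25 + t)
}

## dF/dx in pN/nm, used by Newton solvers. Inputs as wlcForce.
.wlcStiffness <- function(extension, params) {
  kT <- thermalEnergy(params@temperature)
  t <- extension / params@contourLength
  (kT / params@persistenceLength) * (0.5 / (1 - t)^3 + 1) /
    params@contourLength
}

#' Extension of a worm-like chain at a given force
#'
#' Numerical inverse of \code{\link{wlcForce}}: the unique extension in
#' [0, Lc) at which the Marko-Siggia force equals the requested force,
#' solved to 1e-9 relative accuracy by safeguarded Newton iteration.
#' Vectorized over \code{force}.
#'
#' @param force force in pN (>= 0); vectorized.
#' @param params a \linkS4class{WLCParams} object.
#' @return Extension in nm.
#' @examples
#' wlcExtension(12.86, WLCParams(0.4, 100, 298))  # ~50 nm
#' @export
wlcExtension <- function(force, params) {
  stopifnot(is(params, "WLCParams"))
  if (any(!is.finite(force)))
    stop("force must be finite")
  if (any(force < 0))
    stop("force must be >= 0")
  Lc <- params@contourLength
  kT <- thermalEnergy(params@temperature)
  Lp <- params@persistenceLength
  f <- force * Lp / kT               # dimensionless force
  ## initial guess: low-force linear response capped against the
  ## high-force 1 - 1/(2 sqrt(f)) asymptote
  t <- ifelse(f < 0.25, 1.5 * f, pmax(0.5, 1 - 0.5 / sqrt(pmax(f, 0.25))))
  t <- pmin(pmax(t, 0), 1 - 1e-12)
  lo <- rep(0, length(f))
  hi <- rep(1 - 1e-15, length(f))
  g <- function(t) 0.25 / (1 - t)^2 - 0.25 + t - f
  gp <- function(t) 0.5 / (1 - t)^3 + 1
  for (iter in 1:200) {
    val <- g(t)
    lo <- ifelse(val < 0, t, lo)
    hi <- ifelse(val > 0, t, hi)
    step <- val / gp(t)
    tn <- t - step
    bad <- !is.finite(tn) | tn <= lo | tn >= hi
    tn[bad] <- (lo[bad] + hi[bad]) / 2      # bisection safeguard
    if (max(abs(tn - t)) < 1e-14) { t <- tn; break }
    t <- tn
  }
  out <- t * Lc
  out[force == 0] <- 0
  out
}

#' Contour-length gain expected from unfolding a residue span
#'
#' Converts a number of residues into the contour length their unfolding
#' releases: \code{n * perResidue - foldedCorrection}, floored at zero. The
#' folded correction accounts for the end-to-end size the folded structure
#' already contributed to the tether. With the span of 124 residues bridged
#' by the R7-R8 disulphide clamp this arithmetic brackets the expected
#' 38-50 nm loss of unfolding length when the clamp holds.
#'
#' @param nResidues residue count (>= 0).
#' @param perResidue contour length per residue, nm (default 0.365). Values
#'   outside the plausible 0.3-0.45 nm window trigger a warning, not an
#'   error.
#' @param foldedCorrection folded end-to-end size subtracted from the gain,
#'   nm (default 4.5, >= 0).
#' @return Contour-length gain in nm.
#' @examples
#' residuesToContourGain(124, 0.40, 0)    # 49.6 nm, upper-edge assumptions
#' residuesToContourGain(124, 0.34, 4.0)  # 38.16 nm, lower-edge assumptions
#' @export
residuesToContourGain <- function(nResidues, perResidue = 0.365,
                                  foldedCorrection = 4.5) {
  if (any(nResidues < 0)) stop("nResidues must be >= 0")
  if (any(foldedCorrection < 0)) stop("foldedCorrection must be >= 0")
  if (any(perResidue < 0.3 | perResidue > 0.45))
    warning("perResidue outside the plausible 0.3-0.45 nm/residue window")
  pmax(0, nResidues * perResidue - foldedCorrection)
}
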