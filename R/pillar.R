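#' @include AllClasses.R
NULL

#' Nominal pillar node positions of a grid
#'
#' Nodes are laid out row-major on a square lattice with one pillar-spacing
#' margin on every side. Positions are in pixel units, 0-based, x along
#' columns and y along rows, origin at the centre of pixel (0, 0).
#'
#' @param grid a \linkS4class{PillarGrid}.
#' @return Matrix [pillar, (x, y)] in px.
#' @export
pillarNodes <- function(grid) {
  sp <- .spacingPx(grid)
  xs <- sp + (seq_len(grid@nx) - 1) * sp
  ys <- sp + (seq_len(grid@ny) - 1) * sp
  nodes <- as.matrix(expand.grid(x = xs, y = ys))
  dimnames(nodes) <- list(NULL, c("x", "y"))
  nodes
}

#' Circular cell mask over a pillar grid
#'
#' Marks the pillars lying under a synthetic circular "cell" centred on the
#' array.
#'
#' @param grid a \linkS4class{PillarGrid}.
#' @param radiusFraction cell radius as a fraction of the smaller array
#'   dimension.
#' @return Logical vector, one entry per pillar.
#' @export
circularCellMask <- function(grid, radiusFraction = 0.3) {
  nodes <- pillarNodes(grid)
  ctr <- colMeans(nodes)
  r <- radiusFraction * min(grid@nx, grid@ny) * .spacingPx(grid)
  sqrt((nodes[, 1] - ctr[1])^2 + (nodes[, 2] - ctr[2])^2) <= r
}

#' Radially contractile displacement field
#'
#' A time-varying displacement field emulating a contracting cell: each
#' cell-mask pillar is displaced toward the mask centroid with magnitude
#' \code{amplitude * sin(pi * (f - 1) / (nFrames - 1))}, so displacements
#' start at zero, peak at \code{amplitude} mid-movie, and relax. Pillars
#' outside the mask do not move.
#'
#' @param nodes matrix [pillar, (x, y)] px.
#' @param cellMask logical per pillar.
#' @param amplitude peak displacement, px.
#' @param nFrames number of frames.
#' @return Array [pillar, (x, y), frame] of displacements in px.
#' @export
radialContractionField <- function(nodes, cellMask, amplitude, nFrames) {
  np <- nrow(nodes)
  ctr <- colMeans(nodes[cellMask, , drop = FALSE])
  dir <- cbind(ctr[1] - nodes[, 1], ctr[2] - nodes[, 2])
  len <- sqrt(rowSums(dir^2))
  len[len == 0] <- 1
  dir <- dir / len
  dir[!cellMask, ] <- 0
  field <- array(0, dim = c(np, 2, nFrames))
  for (f in seq_len(nFrames)) {
    a <- amplitude * sin(pi * (f - 1) / (nFrames - 1))
    field[, , f] <- dir * a
  }
  field
}

#' Generate a synthetic pillar movie with ground truth
#'
#' Renders each frame as a constant background plus one Gaussian spot per
#' pillar at node + displacement + drift, plus i.i.d. Gaussian noise. The
#' true subpixel positions are stored alongside the stack so localization
#' and force recovery can be verified. Displacement fields whose magnitude
#' reaches half the pillar spacing are refused (tracking would be
#' ill-posed).
#'
#' @param grid a \linkS4class{PillarGrid}.
#' @param displacementField array [pillar, (x, y), frame] in px (e.g. from
#'   \code{\link{radialContractionField}}), or NULL for a static array.
#' @param drift either a length-2 per-frame drift increment (px/frame) or a
#'   matrix [frame, (x, y)] of cumulative drift; NULL for none.
#' @param noiseSd Gaussian intensity noise sd, a.u. (the spot amplitude
#'   over this sd is the SNR).
#' @param nFrames number of frames (>= 2).
#' @param seed RNG seed for the noise.
#' @param cellMask logical per pillar; default
#'   \code{\link{circularCellMask}}.
#' @return A \linkS4class{PillarMovie}.
#' @export
generatePillarMovie <- function(grid, displacementField = NULL,
                                drift = NULL, noiseSd = 0, nFrames = 20,
                                seed = 1,
                                cellMask = circularCellMask(grid)) {
  stopifnot(is(grid, "PillarGrid"), nFrames >= 2)
  nodes <- pillarNodes(grid)
  np <- nrow(nodes)
  sp <- .spacingPx(grid)
  if (is.null(displacementField))
    displacementField <- array(0, dim = c(np, 2, nFrames))
  stopifnot(all(dim(displacementField) == c(np, 2, nFrames)))
  mag <- sqrt(displacementField[, 1, ]^2 + displacementField[, 2, ]^2)
  if (max(mag) >= sp / 2)
    stop("displacement field reaches half the pillar spacing; ",
         "tracking would be ill-posed")
  if (is.null(drift)) {
    drift <- matrix(0, nFrames, 2)
  } else if (is.numeric(drift) && length(drift) == 2L) {
    drift <- cbind((seq_len(nFrames) - 1) * drift[1],
                   (seq_len(nFrames) - 1) * drift[2])
  }
  stopifnot(nrow(drift) == nFrames, ncol(drift) == 2)

  wpx <- ceiling(max(nodes[, 1]) + sp)
  hpx <- ceiling(max(nodes[, 2]) + sp)
  truth <- array(NA_real_, dim = c(np, 2, nFrames))
  frames <- array(0, dim = c(hpx, wpx, nFrames))
  halo <- ceiling(5 * grid@psfSigma)
  withSeed(seed, {
    for (f in seq_len(nFrames)) {
      img <- matrix(grid@background, hpx, wpx)
      for (p in seq_len(np)) {
        x0 <- nodes[p, 1] + displacementField[p, 1, f] + drift[f, 1]
        y0 <- nodes[p, 2] + displacementField[p, 2, f] + drift[f, 2]
        truth[p, , f] <- c(x0, y0)
        cols <- max(0, floor(x0) - halo):min(wpx - 1, ceiling(x0) + halo)
        rows <- max(0, floor(y0) - halo):min(hpx - 1, ceiling(y0) + halo)
        gx <- exp(-(cols - x0)^2 / (2 * grid@psfSigma^2))
        gy <- exp(-(rows - y0)^2 / (2 * grid@psfSigma^2))
        img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] +
          grid@amplitude * outer(gy, gx)
      }
      if (noiseSd > 0)
        img <- img + matrix(stats::rnorm(hpx * wpx, 0, noiseSd), hpx, wpx)
      frames[, , f] <- img
    }
  })
  new("PillarMovie", frames = frames, truth = truth, nodes = nodes,
      drift = drift, cellMask = cellMask, grid = grid)
}

## ---------------------------------------------------------------------------
## Localization
## ---------------------------------------------------------------------------

## Fit b + A exp(-((x-x0)^2+(y-y0)^2)/(2 s^2)) to one window.
.fitSpot <- function(sub, cols, rows, sigma0) {
  border <- c(sub[1, ], sub[nrow(sub), ], sub[, 1], sub[, ncol(sub)])
  bg <- stats::median(border)
  peak <- max(sub) - bg
  thresh <- max(3 * stats::sd(border), 1e-9 * max(abs(sub), 1))
  if (!is.finite(peak) || peak <= thresh) return(c(NA_real_, NA_real_))
  w <- pmax(sub - bg, 0)
  cx <- sum(outer(rep(1, nrow(sub)), cols) * w) / sum(w)
  cy <- sum(outer(rows, rep(1, ncol(sub))) * w) / sum(w)
  dat <- data.frame(I = as.vector(sub),
                    X = as.vector(outer(rep(1, nrow(sub)), cols)),
                    Y = as.vector(outer(rows, rep(1, ncol(sub)))))
  fit <- tryCatch({
    fm <- minpack.lm::nlsLM(
      I ~ b + A * exp(-((X - x0)^2 + (Y - y0)^2) / (2 * s^2)), data = dat,
      start = list(b = bg, A = peak, x0 = cx, y0 = cy, s = sigma0),
      control = minpack.lm::nls.lm.control(maxiter = 100))
    cf <- stats::coef(fm)
    c(unname(cf["x0"]), unname(cf["y0"]))
  }, error = function(e) c(cx, cy))   # centroid fallback
  fit
}

#' Subpixel spot localization around nominal nodes
#'
#' For each nominal node, extracts a square window, estimates the
#' background from the window border, initializes with the
#' background-subtracted intensity centroid and refines by least-squares
#' 2-D Gaussian fitting. Windows with no signal above background yield a
#' missing (NA) position.
#'
#' @param frame numeric matrix [rows, cols].
#' @param nodes matrix [pillar, (x, y)] of nominal positions, px (0-based).
#' @param window window edge length, px (odd).
#' @param psfSigma starting Gaussian sigma for the refinement, px.
#' @return Matrix [pillar, (x, y)] of subpixel positions, px; NA rows mark
#'   missing detections.
#' @export
localizeSpots <- function(frame, nodes, window = 9, psfSigma = 1.3) {
  stopifnot(is.matrix(frame), window %% 2 == 1)
  w <- (window - 1) / 2
  out <- matrix(NA_real_, nrow(nodes), 2,
                dimnames = list(NULL, c("x", "y")))
  for (p in seq_len(nrow(nodes))) {
    cx <- round(nodes[p, 1]); cy <- round(nodes[p, 2])
    cols <- (cx - w):(cx + w)
    rows <- (cy - w):(cy + w)
    keepc <- cols >= 0 & cols <= ncol(frame) - 1
    keepr <- rows >= 0 & rows <= nrow(frame) - 1
    cols <- cols[keepc]; rows <- rows[keepr]
    if (length(cols) < 5 || length(rows) < 5) next
    sub <- frame[rows + 1, cols + 1, drop = FALSE]
    out[p, ] <- .fitSpot(sub, cols, rows, psfSigma)
  }
  out
}

#' Track all pillars through a movie
#'
#' Sequential localization across frames: each frame's windows are centred
#' on the positions found in the previous frame (starting from the nominal
#' nodes), so slowly drifting spots stay inside their windows; the
#' per-frame detections are then linked into tracks.
#'
#' @param stack numeric array [rows, cols, frames] or a
#'   \linkS4class{PillarMovie}.
#' @param grid a \linkS4class{PillarGrid}.
#' @param window,psfSigma localization settings, see
#'   \code{\link{localizeSpots}}.
#' @return A \linkS4class{PillarTrackSet} (not yet drift-corrected).
#' @export
trackPillarMovie <- function(stack, grid, window = 9,
                             psfSigma = grid@psfSigma) {
  if (is(stack, "PillarMovie")) stack <- stack@frames
  nodes <- pillarNodes(grid)
  nf <- dim(stack)[3]
  dets <- vector("list", nf)
  prev <- nodes
  for (f in seq_len(nf)) {
    det <- localizeSpots(stack[, , f], prev, window, psfSigma)
    dets[[f]] <- det
    ok <- stats::complete.cases(det)
    prev[ok, ] <- det[ok, ]
  }
  linkTracks(dets, grid)
}

## ---------------------------------------------------------------------------
## Linking, drift correction, forces
## ---------------------------------------------------------------------------

#' Link per-frame detections into pillar tracks
#'
#' Frame-0 detections are assigned to their nearest nominal node; later
#' frames are linked to the previous position of each track by
#' nearest-neighbour assignment with a gate of half the pillar spacing.
#' Missing detections are linearly interpolated (constant-extrapolated at
#' the ends) and flagged. Assignment ties inside the gate are broken by
#' distance and counted in the \code{ties} attribute.
#'
#' @param perFramePositions list (one entry per frame) of detection
#'   matrices [spot, (x, y)] px, e.g. from \code{\link{localizeSpots}}.
#' @param grid a \linkS4class{PillarGrid}.
#' @return A \linkS4class{PillarTrackSet} (not yet drift-corrected).
#' @export
linkTracks <- function(perFramePositions, grid) {
  stopifnot(is.list(perFramePositions), length(perFramePositions) >= 2)
  nodes <- pillarNodes(grid)
  np <- nrow(nodes)
  nf <- length(perFramePositions)
  gate <- .spacingPx(grid) / 2
  pos <- array(NA_real_, dim = c(np, 2, nf))
  interp <- matrix(FALSE, np, nf)
  ties <- 0L
  prev <- nodes
  for (f in seq_len(nf)) {
    det <- perFramePositions[[f]]
    ok <- stats::complete.cases(det)
    detOK <- det[ok, , drop = FALSE]
    used <- rep(FALSE, nrow(detOK))
    for (p in seq_len(np)) {
      if (nrow(detOK) == 0) break
      d2 <- (detOK[, 1] - prev[p, 1])^2 + (detOK[, 2] - prev[p, 2])^2
      cand <- which(d2 <= gate^2 & !used)
      if (length(cand) == 0) next
      if (length(cand) > 1) ties <- ties + 1L
      best <- cand[which.min(d2[cand])]
      pos[p, , f] <- detOK[best, ]
      used[best] <- TRUE
    }
    miss <- is.na(pos[, 1, f])
    interp[miss, f] <- TRUE
    prev[!miss, ] <- pos[!miss, , f]
  }
  ## fill missing samples by linear interpolation along each track
  for (p in seq_len(np)) {
    for (k in 1:2) {
      v <- pos[p, k, ]
      if (anyNA(v)) {
        if (all(is.na(v))) v <- rep(nodes[p, k], nf)
        else v <- stats::approx(which(!is.na(v)), v[!is.na(v)],
                                xout = seq_len(nf), rule = 2)$y
        pos[p, k, ] <- v
      }
    }
  }
  out <- new("PillarTrackSet", positions = pos, nodes = nodes,
             isReference = rep(FALSE, np), interpolated = interp,
             driftCorrected = FALSE, grid = grid)
  attr(out, "ties") <- ties
  out
}

#' Correct stage drift using cell-free reference pillars
#'
#' Estimates the rigid stage drift per frame as the mean displacement
#' (relative to frame 0) of the reference pillars - pillars in a region
#' free of cells - and subtracts it from every track. After correction the
#' mean reference displacement is identically zero in every frame.
#'
#' @param tracks a \linkS4class{PillarTrackSet}.
#' @param referenceIds indices of at least 3 reference pillars.
#' @return The drift-corrected \linkS4class{PillarTrackSet}.
#' @export
correctDrift <- function(tracks, referenceIds) {
  stopifnot(is(tracks, "PillarTrackSet"))
  if (length(referenceIds) < 3)
    stop("drift correction needs at least 3 reference pillars")
  pos <- tracks@positions
  nf <- dim(pos)[3]
  disp0 <- pos - pos[, , rep(1L, nf), drop = FALSE]
  refDrift <- apply(disp0[referenceIds, , , drop = FALSE], c(2, 3), mean)
  for (f in seq_len(nf)) {
    pos[, 1, f] <- pos[, 1, f] - refDrift[1, f]
    pos[, 2, f] <- pos[, 2, f] - refDrift[2, f]
  }
  tracks@positions <- pos
  tracks@isReference <- seq_len(dim(pos)[1]) %in% referenceIds
  tracks@driftCorrected <- TRUE
  tracks
}

#' Convert pillar displacements to traction forces
#'
#' Displacements are measured against frame 0 (the zero-force reference)
#' and converted to nm; forces follow by multiplying the displacements by
#' the pillar stiffness, componentwise, so |force| = stiffness *
#' |displacement| exactly. The peak force per pillar is the maximum
#' magnitude over frames and the cell-average force is the mean of the peak
#' forces over the cell-mask pillars.
#'
#' @param tracks a drift-corrected \linkS4class{PillarTrackSet}.
#' @param grid a \linkS4class{PillarGrid} (supplies stiffness and pixel
#'   size).
#' @param cellMask logical per pillar marking pillars under the cell.
#' @param requireDriftCorrected refuse tracks that have not been
#'   drift-corrected (default TRUE).
#' @return A \linkS4class{ForceMap}.
#' @export
displacementsToForces <- function(tracks, grid, cellMask,
                                  requireDriftCorrected = TRUE) {
  stopifnot(is(tracks, "PillarTrackSet"), is(grid, "PillarGrid"))
  if (requireDriftCorrected && !tracks@driftCorrected)
    stop("tracks must be drift-corrected first (see correctDrift)")
  pos <- tracks@positions
  np <- dim(pos)[1]; nf <- dim(pos)[3]
  stopifnot(length(cellMask) == np)
  nmPerPx <- grid@pixelSize * 1000
  disp <- (pos - pos[, , rep(1L, nf), drop = FALSE]) * nmPerPx   # nm
  forces <- disp * grid@stiffness / 1000                         # nN
  mag <- sqrt(forces[, 1, ]^2 + forces[, 2, ]^2)
  peak <- apply(mag, 1, max, na.rm = TRUE)
  cellMean <- mean(peak[cellMask])
  new("ForceMap", displacements = disp, forces = forces, peakForce = peak,
      cellMask = cellMask, cellMean = cellMean, stiffness = grid@stiffness)
}

## ---------------------------------------------------------------------------
## TIFF round trip and rendering
## ---------------------------------------------------------------------------

#' Write a pillar movie as a multi-frame 16-bit TIFF
#'
#' Intensities are scaled by 1/65535 for storage;
#' \code{\link{readPillarStack}} restores the original scale.
#'
#' @param movie a \linkS4class{PillarMovie} or a numeric array
#'   [rows, cols, frames].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePillarMovie <- function(movie, path) {
  frames <- if (is(movie, "PillarMovie")) movie@frames else movie
  lst <- lapply(seq_len(dim(frames)[3]), function(f)
    pmin(pmax(frames[, , f] / 65535, 0), 1))
  tiff::writeTIFF(lst, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-frame TIFF written by \code{\link{writePillarMovie}}
#'
#' @param path TIFF file.
#' @return Numeric array [rows, cols, frames] on the original intensity
#'   scale.
#' @export
readPillarStack <- function(path) {
  lst <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(lst)) lst <- list(lst)
  arr <- array(0, dim = c(nrow(lst[[1]]), ncol(lst[[1]]), length(lst)))
  for (f in seq_along(lst)) arr[, , f] <- lst[[f]] * 65535
  arr
}

#' Render a peak-force heat map
#'
#' Draws the pillar array coloured by per-pillar peak force; writes a PNG
#' when a path is given.
#'
#' @param map a \linkS4class{ForceMap}.
#' @param nodes matrix [pillar, (x, y)] px.
#' @param path optional PNG output path.
#' @return The per-pillar peak forces, invisibly.
#' @export
plotForceHeatmap <- function(map, nodes, path = NULL) {
  pk <- peakForces(map)
  if (!is.null(path)) {
    grDevices::png(path, width = 480, height = 480)
    on.exit(grDevices::dev.off())
  }
  pal <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE)
  idx <- pmax(1L, pmin(64L, 1L + floor(63 * pk / max(pk, 1e-12))))
  graphics::plot(nodes[, 1], -nodes[, 2], pch = 16, cex = 1.6,
                 col = pal[idx], asp = 1, xlab = "x (px)", ylab = "-y (px)",
                 main = sprintf("Peak pillar forces (max %.2f nN)", max(pk)))
  invisible(pk)
}
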