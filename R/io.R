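#' @include AllClasses.R
NULL

.traceHeader <- c("time_s", "piezo_nm", "force_pN", "extension_nm")

#' Write a force-extension trace as a columnar file
#'
#' CSV with header \code{time_s,piezo_nm,force_pN,extension_nm}. When the
#' trace carries ground-truth events they are written to a
#' \code{<path>.events.csv} sidecar (domain, index, time_s, force_pN,
#' delta_lc_nm).
#'
#' @param trace a \linkS4class{ForceExtensionTrace}.
#' @param path output CSV path.
#' @param sidecar also write the ground-truth sidecar when events exist.
#' @return \code{path}, invisibly.
#' @export
writeTraceFile <- function(trace, path, sidecar = TRUE) {
  stopifnot(is(trace, "ForceExtensionTrace"))
  df <- data.frame(time_s = trace@time, piezo_nm = trace@piezo,
                   force_pN = trace@force, extension_nm = trace@extension)
  names(df) <- .traceHeader
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  gt <- groundTruth(trace)
  if (sidecar && nrow(gt) > 0) {
    out <- data.frame(domain = gt$domain, index = gt$index,
                      time_s = gt$time, force_pN = gt$force,
                      delta_lc_nm = gt$deltaLc)
    utils::write.csv(out, paste0(path, ".events.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read a force-extension trace file
#'
#' Expects the documented schema (\code{time_s,piezo_nm,force_pN,
#' extension_nm}); missing columns raise a schema error and non-numeric
#' cells are reported with their line number. A \code{<path>.events.csv}
#' sidecar, when present, is loaded as the ground-truth event table.
#'
#' @param path trace CSV.
#' @param cantileverStiffness optional stiffness to attach, pN/nm.
#' @return A \linkS4class{ForceExtensionTrace}.
#' @export
readTraceFile <- function(path, cantileverStiffness = NA_real_) {
  if (!file.exists(path)) stop("no such trace file: ", path)
  raw <- tryCatch(
    utils::read.csv(path, colClasses = "character", strip.white = TRUE),
    error = function(e) stop("schema error reading ", path, ": ",
                             conditionMessage(e)))
  if (nrow(raw) == 0 && ncol(raw) == 0)
    stop("schema error: ", path, " is empty")
  missingCols <- setdiff(.traceHeader, names(raw))
  if (length(missingCols))
    stop("schema error in ", path, ": missing columns ",
         paste(missingCols, collapse = ", "))
  cols <- lapply(.traceHeader, function(cn) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !(raw[[cn]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("malformed value in column '%s' at line %d of %s",
                   cn, bad[1] + 1L, path))
    v
  })
  names(cols) <- .traceHeader
  side <- paste0(path, ".events.csv")
  gt <- if (file.exists(side)) {
    s <- utils::read.csv(side, stringsAsFactors = FALSE)
    data.frame(domain = s$domain, index = as.integer(s$index),
               time = s$time_s, force = s$force_pN,
               deltaLc = s$delta_lc_nm, stringsAsFactors = FALSE)
  } else .emptyGroundTruth()
  new("ForceExtensionTrace", time = cols$time_s, piezo = cols$piezo_nm,
      force = cols$force_pN, extension = cols$extension_nm,
      cantileverStiffness = as.numeric(cantileverStiffness),
      groundTruth = gt)
}

#' Write a FRAP curve as a columnar file
#'
#' CSV with header \code{time_s,intensity,role} where role is prebleach or
#' postbleach.
#'
#' @param curve a \linkS4class{FRAPCurve}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFrapCurve <- function(curve, path) {
  stopifnot(is(curve, "FRAPCurve"))
  role <- ifelse(seq_along(curve@times) <= curve@nPrebleach,
                 "prebleach", "postbleach")
  utils::write.csv(data.frame(time_s = curve@times,
                              intensity = curve@intensities, role = role),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FRAP curve file written by \code{\link{writeFrapCurve}}
#'
#' @param path curve CSV.
#' @param background background level to record, a.u.
#' @param normalized whether the stored intensities are normalized.
#' @return A \linkS4class{FRAPCurve}.
#' @export
readFrapCurve <- function(path, background = 0, normalized = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "intensity", "role")
  if (!all(need %in% names(df)))
    stop("schema error in ", path, ": need columns ",
         paste(need, collapse = ", "))
  FRAPCurve(df$time_s, df$intensity,
            nPrebleach = sum(df$role == "prebleach"),
            background = background, normalized = normalized)
}

#' Write pillar tracks (and optionally forces) as a columnar file
#'
#' One row per pillar and frame: \code{pillar_id,frame,x_px,y_px} plus
#' \code{dx_nm,dy_nm,fx_nN,fy_nN} when a \linkS4class{ForceMap} is given.
#'
#' @param tracks a \linkS4class{PillarTrackSet}.
#' @param path output path.
#' @param map optional matching \linkS4class{ForceMap}.
#' @return \code{path}, invisibly.
#' @export
writeTrackTable <- function(tracks, path, map = NULL) {
  stopifnot(is(tracks, "PillarTrackSet"))
  pos <- tracks@positions
  np <- dim(pos)[1]; nf <- dim(pos)[3]
  df <- data.frame(
    pillar_id = rep(seq_len(np), nf),
    frame = rep(seq_len(nf) - 1L, each = np),
    x_px = as.vector(pos[, 1, ]), y_px = as.vector(pos[, 2, ]))
  if (!is.null(map)) {
    df$dx_nm <- as.vector(map@displacements[, 1, ])
    df$dy_nm <- as.vector(map@displacements[, 2, ])
    df$fx_nN <- as.vector(map@forces[, 1, ])
    df$fy_nN <- as.vector(map@forces[, 2, ])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a track table written by \code{\link{writeTrackTable}}
#'
#' @param path track CSV.
#' @return data.frame with one row per pillar and frame.
#' @export
readTrackTable <- function(path) {
  df <- utils::read.csv(path)
  need <- c("pillar_id", "frame", "x_px", "y_px")
  if (!all(need %in% names(df)))
    stop("schema error in ", path, ": need columns ",
         paste(need, collapse = ", "))
  df
}
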