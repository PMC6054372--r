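#' @include AllClasses.R wlc.R
NULL

#' Default talin R7-R8 polyprotein construct
#'
#' Builds the study construct: the talin rod R7-R8 region flanked by two
#' I27 titin fingerprint domains and an always-unfolded handle (HaloTag plus
#' linkers). The R8 release defaults to the 124-residue span bridged by the
#' Q1459C/S1583C disulphide clamp at 0.36 nm/residue minus a 4.5 nm folded
#' correction (40.1 nm); R7 is set independently so the wild-type construct
#' releases ~104 nm of talin contour in total. With \code{clamped = TRUE}
#' the R8 bundle carries the disulphide clamp and releases nothing.
#'
#' Bell kinetic constants are not measured quantities of the study; the
#' defaults place talin ruptures near 20 pN and I27 ruptures near 200 pN
#' under the 400 nm/s, ~7 pN/nm protocol.
#'
#' @param clamped apply the R8 disulphide clamp.
#' @param perResidue,foldedCorrection passed to
#'   \code{\link{residuesToContourGain}} for the R8 release.
#' @param r7DeltaLc contour released by R7 unfolding, nm.
#' @param handleContour handle contour, nm.
#' @param talinK0,talinDx Bell parameters shared by the talin bundles.
#' @param i27K0,i27Dx,i27DeltaLc Bell parameters and release of the I27
#'   fingerprints.
#' @return A \linkS4class{PolyproteinConstruct}.
#' @examples
#' wt <- talinR7R8Construct()
#' cl <- talinR7R8Construct(clamped = TRUE)
#' releasableContour(wt) - releasableContour(cl)  # the R8 release
#' @export
talinR7R8Construct <- function(clamped = FALSE, perResidue = 0.36,
                               foldedCorrection = 4.5, r7DeltaLc = 63.9,
                               handleContour = 30,
                               talinK0 = 0.06, talinDx = 1.5,
                               i27K0 = 3.3e-4, i27Dx = 0.25,
                               i27DeltaLc = 28.0) {
  r8Release <- residuesToContourGain(124, perResidue, foldedCorrection)
  i27 <- function(nm) FoldableDomain(nm, 89, i27DeltaLc, i27K0, i27Dx,
                                     foldedSize = 4.5)
  r7 <- FoldableDomain("R7", 190, r7DeltaLc, talinK0, talinDx,
                       foldedSize = 4.5)
  r8 <- FoldableDomain("R8", 124, r8Release, talinK0, talinDx,
                       foldedSize = 4.5, clamped = clamped,
                       clampSpan = if (clamped) 124 else 0)
  PolyproteinConstruct(list(i27("I27a"), r7, r8, i27("I27b")),
                       handleContour = handleContour)
}

## ---------------------------------------------------------------------------
## Construct file format: versioned structured text
## ---------------------------------------------------------------------------

.constructSchema <- "MechanoKit-construct-v1"

#' Write a polyprotein construct definition
#'
#' Writes a versioned structured-text record: a schema header, the handle
#' contour, and one tab-separated row per domain (name, n_residues,
#' delta_lc_nm, k0_per_s, dx_nm, folded_size_nm, clamped,
#' clamp_span_residues).
#'
#' @param construct a \linkS4class{PolyproteinConstruct}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeConstructFile <- function(construct, path) {
  stopifnot(is(construct, "PolyproteinConstruct"))
  tab <- do.call(rbind, lapply(domains(construct), function(d) {
    data.frame(name = d@name, n_residues = d@nResidues,
               delta_lc_nm = d@deltaLc, k0_per_s = d@k0, dx_nm = d@dx,
               folded_size_nm = d@foldedSize, clamped = d@clamped,
               clamp_span_residues = d@clampSpan, stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# schema: ", .constructSchema),
               sprintf("# handle_contour_nm: %.10g",
                       handleContour(construct))), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a polyprotein construct definition
#'
#' @param path file written by \code{\link{writeConstructFile}}.
#' @return A \linkS4class{PolyproteinConstruct}.
#' @export
readConstructFile <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !grepl(.constructSchema, lines[1], fixed = TRUE))
    stop("not a ", .constructSchema, " file: ", path)
  hline <- grep("^# handle_contour_nm:", lines, value = TRUE)
  if (length(hline) != 1L)
    stop("construct file is missing the handle_contour_nm header")
  handle <- as.numeric(sub("^# handle_contour_nm:\\s*", "", hline))
  tab <- utils::read.table(textConnection(lines[!grepl("^#", lines)]),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("name", "n_residues", "delta_lc_nm", "k0_per_s", "dx_nm",
            "folded_size_nm", "clamped", "clamp_span_residues")
  if (!all(need %in% names(tab)))
    stop("construct file is missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  doms <- lapply(seq_len(nrow(tab)), function(i) {
    FoldableDomain(tab$name[i], tab$n_residues[i], tab$delta_lc_nm[i],
                   tab$k0_per_s[i], tab$dx_nm[i], tab$folded_size_nm[i],
                   clamped = as.logical(tab$clamped[i]),
                   clampSpan = tab$clamp_span_residues[i])
  })
  PolyproteinConstruct(doms, handleContour = handle)
}
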