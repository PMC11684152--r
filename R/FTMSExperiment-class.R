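#' FTMSExperiment: container for formula-assigned FT-MS peak data
#'
#' An `FTMSExperiment` extends \linkS4class{SummarizedExperiment}.  The
#' `"intensity"` assay is the peak table: rows are peaks keyed by a unique
#' mass identifier (rownames), columns are samples.  `rowData` is the
#' molecular identification table: element counts `C`, `H`, `N`, `O`, `S`,
#' `P` (non-negative integers, `NA` for peaks without an assigned formula),
#' an optional `Formula` string, an optional isotope column, an optional
#' numeric `Mass`, and any calculated-property columns appended by
#' [calculateProperties()].
#'
#' @slot dataScale scale of the intensities: one of `"abundance"`,
#'   `"log2"`, `"log10"`, `"ln"`, `"presence_absence"`.
#' @slot missingCode the raw value that encodes "peak not observed" in the
#'   uploaded data (typically 0).
#' @slot missingEncoded has [encodeMissing()] been applied, i.e. are
#'   unobserved cells now `NA`?
#' @slot provenance append-only list of processing-step records, each a list
#'   with elements `step`, `params`, `peaksBefore`, `peaksAfter`,
#'   `samplesBefore`, `samplesAfter`, `timestamp`.
#'
#' @section Invariants:
#' Mass identifiers are unique and shared between the peak table and the
#' molecular table (enforced by the common rownames).  Wherever a formula is
#' recorded, `C >= 1` and `H >= 1`.  After missing encoding every cell is a
#' finite observed value or `NA`.
#'
#' @seealso [readGeneralizedInput()], [pivotToDataset()], [simulateDataset()]
#' @export
setClass("FTMSExperiment",
  contains = "SummarizedExperiment",
  slots = c(
    dataScale = "character",
    missingCode = "numeric",
    missingEncoded = "logical",
    provenance = "list"
  ),
  prototype = prototype(
    dataScale = "abundance",
    missingCode = 0,
    missingEncoded = FALSE,
    provenance = list()
  )
)

setValidity("FTMSExperiment", function(object) {
  msg <- character()
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  ids <- rownames(object)
  if (is.null(ids))
    msg <- c(msg, "mass identifiers (rownames) are required")
  else if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate mass identifiers: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  rd <- rowData(object)
  if (!all(c("C", "H") %in% colnames(rd))) {
    msg <- c(msg, "C and H are required in the molecular table")
  } else {
    C <- rd$C; H <- rd$H
    has <- !is.na(C) | !is.na(H)
    bad <- has & (is.na(C) | is.na(H) | C < 1 | H < 1)
    if (any(bad))
      msg <- c(msg, paste0("C and H are required (C >= 1, H >= 1) wherever a ",
                           "formula is recorded; offending peaks: ",
                           paste(head(ids[bad], 5), collapse = ", ")))
  }
  if (length(object@dataScale) != 1L ||
      !object@dataScale %in% .DATA_SCALES)
    msg <- c(msg, paste0("dataScale must be one of: ",
                         paste(.DATA_SCALES, collapse = ", ")))
  if (length(object@missingCode) != 1L)
    msg <- c(msg, "missingCode must be a single value")
  if (length(msg)) msg else TRUE
})

#' Construct an FTMSExperiment
#'
#' @param peakTable numeric matrix of intensities, rows = peaks (rownames =
#'   mass identifiers), columns = samples.
#' @param molTable `data.frame` or `DataFrame` of molecular identification
#'   data, one row per peak in `peakTable` order (or with matching
#'   rownames).  Must contain `C` and `H` columns (use
#'   [parseMolecularFormula()] to derive them from formula strings).
#' @param dataScale scale of the intensities (see class docs).
#' @param missingCode raw value encoding "not observed"; default 0.
#' @param missingEncoded whether unobserved cells are already `NA`.
#' @param provenance optional initial provenance list.
#' @return an [FTMSExperiment-class] object.
#' @examples
#' pt <- matrix(c(10, 0, 3, 8), 2, 2,
#'              dimnames = list(c("m1", "m2"), c("s1", "s2")))
#' mt <- data.frame(C = c(6, 10), H = c(12, 14), N = c(0, 2),
#'                  O = c(6, 0), S = 0, P = 0)
#' ds <- FTMSExperiment(pt, mt)
#' ds
#' @export
FTMSExperiment <- function(peakTable, molTable,
                           dataScale = "abundance", missingCode = 0,
                           missingEncoded = FALSE, provenance = list()) {
  peakTable <- as.matrix(peakTable)
  storage.mode(peakTable) <- "double"
  if (is.null(rownames(peakTable)))
    stop("peakTable must have mass identifiers as rownames")
  molTable <- as(molTable, "DataFrame")
  if (!is.null(rownames(molTable)) &&
      !identical(rownames(molTable), as.character(seq_len(nrow(molTable))))) {
    extra <- setdiff(rownames(molTable), rownames(peakTable))
    miss <- setdiff(rownames(peakTable), rownames(molTable))
    if (length(extra) || length(miss))
      stop("mass identifier sets differ between the peak table and the ",
           "molecular table; only in molecular table: ",
           paste(head(extra, 5), collapse = ", "),
           "; only in peak table: ", paste(head(miss, 5), collapse = ", "))
    molTable <- molTable[rownames(peakTable), , drop = FALSE]
  } else if (nrow(molTable) != nrow(peakTable)) {
    stop("molTable must have one row per peak")
  }
  for (el in .ELEMENTS)
    if (!el %in% colnames(molTable))
      molTable[[el]] <- NA_real_
  se <- SummarizedExperiment(assays = list(intensity = peakTable),
                             rowData = molTable)
  new("FTMSExperiment", se, dataScale = dataScale,
      missingCode = as.numeric(missingCode),
      missingEncoded = missingEncoded, provenance = provenance)
}

# ---- accessors --------------------------------------------------------------

#' @describeIn FTMSExperiment the intensity matrix (peaks x samples).
#' @param x,object an `FTMSExperiment`.
#' @export
peakTable <- function(x) assay(x, "intensity")

#' @describeIn FTMSExperiment the molecular identification table
#'   (`DataFrame`, one row per peak) including calculated columns.
#' @export
molTable <- function(x) rowData(x)

#' @describeIn FTMSExperiment replace the molecular identification table
#'   (must keep one row per peak).
#' @param value replacement molecular table.
#' @export
`molTable<-` <- function(x, value) {
  rowData(x) <- as(value, "DataFrame")
  validObject(x)
  x
}

#' @describeIn FTMSExperiment the intensity scale.
#' @export
dataScale <- function(x) x@dataScale

#' @describeIn FTMSExperiment the raw missing-value code.
#' @export
missingCode <- function(x) x@missingCode

#' @describeIn FTMSExperiment has [encodeMissing()] been applied?
#' @export
isMissingEncoded <- function(x) x@missingEncoded

#' @describeIn FTMSExperiment the ordered list of processing-step records.
#' @export
provenance <- function(x) x@provenance

#' Sample group assignments
#'
#' Group labels live in `colData(x)$Group` as a character vector (`NA` =
#' unassigned).  The replacement form accepts a named vector
#' (names = sample identifiers) such as returned by [detectGroups()], or an
#' unnamed vector of length `ncol(x)`.
#'
#' @param x an `FTMSExperiment`.
#' @param value named character vector mapping sample identifiers to group
#'   labels, or unnamed vector of length `ncol(x)`.
#' @return `groups(x)` returns a named character vector (all samples,
#'   `NA` where unassigned).
#' @export
groups <- function(x) {
  g <- colData(x)$Group
  if (is.null(g)) g <- rep(NA_character_, ncol(x))
  names(g) <- colnames(x)
  g
}

#' @rdname groups
#' @export
`groups<-` <- function(x, value) {
  if (!is.null(names(value))) {
    unknown <- setdiff(names(value), colnames(x))
    if (length(unknown))
      stop("group assignment names not among samples: ",
           paste(head(unknown, 5), collapse = ", "))
    g <- setNames(rep(NA_character_, ncol(x)), colnames(x))
    g[names(value)] <- as.character(value)
  } else {
    if (length(value) != ncol(x))
      stop("unnamed group vector must have one entry per sample")
    g <- as.character(value)
  }
  colData(x)$Group <- unname(g)
  x
}

# append one provenance record; counts captured around each processing step
.addStep <- function(x, step, params = list(),
                     before = dim(x), after = dim(x)) {
  rec <- list(step = step, params = params,
              peaksBefore = before[[1L]], peaksAfter = after[[1L]],
              samplesBefore = before[[2L]], samplesAfter = after[[2L]],
              timestamp = .timestamp())
  x@provenance <- c(x@provenance, list(rec))
  x
}

setMethod("show", "FTMSExperiment", function(object) {
  cat("FTMSExperiment with", nrow(object), "peaks and",
      ncol(object), "samples\n")
  cat("  dataScale:", object@dataScale,
      "| missingCode:", object@missingCode,
      "| missing encoded:", object@missingEncoded, "\n")
  nf <- sum(!is.na(rowData(object)$C))
  cat("  peaks with formula:", nf, "\n")
  g <- groups(object)
  if (any(!is.na(g))) {
    tb <- table(g, useNA = "no")
    cat("  groups:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  if (length(object@provenance))
    cat("  provenance:",
        paste(vapply(object@provenance, `[[`, "", "step"), collapse = " -> "),
        "\n")
  invisible(NULL)
})
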