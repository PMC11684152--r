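# Long-format candidate-assignment records (CoreMS-style), standardized to
# columns SampleID, MZ, Intensity, Formula, Confidence, MassError, Isotope.
# Represented as a data.frame with class "CoreMSRecords"; the "resolved"
# attribute records whether resolveFormulas() has been run.

# synonym lists for auto-detecting CoreMS column names; matching is done on
# names normalized to lowercase alphanumerics
.COREMS_SYNONYMS <- list(
  MZ = c("calibratedmz", "mz", "mzcalibrated", "calculatedmz", "mzexp"),
  Intensity = c("peakheight", "intensity", "abundance", "height"),
  Formula = c("molecularformula", "formula", "molform"),
  Confidence = c("confidencescore", "confidence", "score"),
  MassError = c("mzerrorppm", "masserrorppm", "mzerror", "masserror",
                "errorppm"),
  Isotope = c("isisotopologue", "isotopologue", "isotope")
)

.normName <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read CoreMS-style per-sample output files
#'
#' Each file is one sample of long-format candidate assignments: calibrated
#' m/z, peak height, candidate molecular formula, confidence score, mass
#' error (ppm) and isotope annotation.  Column names are auto-detected
#' against a synonym list (case/punctuation-insensitive); an explicit
#' `columnMap` always wins.
#'
#' @param files character vector of CSV paths, one per sample.
#' @param columnMap optional named character vector mapping standard names
#'   (`MZ`, `Intensity`, `Formula`, `Confidence`, `MassError`, `Isotope`) to
#'   column names in the files.
#' @param sampleIds sample identifiers; default: file names without
#'   extension.
#' @return a `CoreMSRecords` data.frame with columns `SampleID`, `MZ`,
#'   `Intensity`, `Formula`, `Confidence`, `MassError`, `Isotope`.
#' @seealso [confidenceProfile()], [applyConfidenceFilter()],
#'   [resolveFormulas()], [pivotToDataset()]
#' @export
readCoreMS <- function(files, columnMap = NULL, sampleIds = NULL) {
  if (length(files) < 1L) stop("at least one file is required")
  if (is.null(sampleIds))
    sampleIds <- file_path_sans_ext(basename(files))
  stopifnot(length(sampleIds) == length(files))
  required <- c("MZ", "Intensity", "Formula", "Confidence")
  optional <- c("MassError", "Isotope")
  recs <- lapply(seq_along(files), function(i) {
    df <- read.csv(files[i], check.names = FALSE)
    norm <- .normName(colnames(df))
    resolve1 <- function(std) {
      if (!is.null(columnMap) && std %in% names(columnMap)) {
        cn <- columnMap[[std]]
        if (!cn %in% colnames(df))
          stop("column '", cn, "' (mapped to ", std, ") not found in ",
               files[i])
        return(cn)
      }
      hit <- which(norm %in% .COREMS_SYNONYMS[[std]])
      if (length(hit)) colnames(df)[hit[1L]] else NA_character_
    }
    found <- vapply(c(required, optional), resolve1, "")
    missingReq <- required[is.na(found[required])]
    if (length(missingReq))
      stop("cannot resolve required column(s) ",
           paste(missingReq, collapse = ", "), " in ", files[i],
           "; columns found: ", paste(colnames(df), collapse = ", "),
           ". Supply a columnMap.")
    out <- data.frame(
      SampleID = sampleIds[i],
      MZ = as.numeric(df[[found["MZ"]]]),
      Intensity = as.numeric(df[[found["Intensity"]]]),
      Formula = as.character(df[[found["Formula"]]]),
      Confidence = as.numeric(df[[found["Confidence"]]]),
      MassError = if (!is.na(found["MassError"]))
        as.numeric(df[[found["MassError"]]]) else NA_real_,
      Isotope = if (!is.na(found["Isotope"]))
        as.character(df[[found["Isotope"]]]) else NA_character_,
      stringsAsFactors = FALSE)
    out
  })
  recs <- do.call(rbind, recs)
  if (any(!is.finite(recs$MZ)) || any(recs$MZ <= 0))
    stop("m/z values must be positive and finite")
  if (any(!is.finite(recs$Confidence)))
    stop("confidence scores must be finite")
  if (any(recs$Confidence < 0 | recs$Confidence > 1))
    stop("confidence scores outside [0,1]; this reader assumes scores on ",
         "the unit interval")
  structure(recs, class = c("CoreMSRecords", "data.frame"),
            resolved = FALSE, provenance = list())
}

#' @export
print.CoreMSRecords <- function(x, ...) {
  cat("CoreMSRecords:", nrow(x), "candidate rows,",
      length(unique(x$SampleID)), "samples",
      if (isTRUE(attr(x, "resolved"))) "(resolved)" else "(unresolved)",
      "\n")
  print.data.frame(head(as.data.frame(x), 6), ...)
  invisible(x)
}

.keepAttrs <- function(new, old, resolved = attr(old, "resolved"),
                       step = NULL) {
  prov <- attr(old, "provenance")
  if (!is.null(step)) prov <- c(prov, list(step))
  structure(as.data.frame(new), class = c("CoreMSRecords", "data.frame"),
            resolved = resolved, provenance = prov)
}

#' Profile candidate retention over a grid of confidence thresholds
#'
#' For each threshold `t`, the number of candidate records with score
#' `>= t` and the mean and maximum absolute mass error among them — the
#' table used to pick a confidence cut-off that minimizes mass error while
#' maximizing peaks retained.
#'
#' @param recs a `CoreMSRecords` object.
#' @param thresholds numeric grid of scores within \[0, 1\].
#' @return data.frame with columns `Threshold`, `Retained`,
#'   `MeanAbsMassError`, `MaxAbsMassError`.
#' @export
confidenceProfile <- function(recs, thresholds = seq(0, 1, by = 0.05)) {
  if (length(thresholds) == 0L) stop("threshold grid is empty")
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie within [0, 1]")
  do.call(rbind, lapply(sort(thresholds), function(t) {
    keep <- recs$Confidence >= t
    err <- abs(recs$MassError[keep])
    data.frame(Threshold = t, Retained = sum(keep),
               MeanAbsMassError = if (any(keep)) mean(err) else NA_real_,
               MaxAbsMassError = if (any(keep)) max(err) else NA_real_)
  }))
}

#' Drop candidate records below a confidence score
#'
#' @param recs a `CoreMSRecords` object.
#' @param minScore minimum confidence score in \[0, 1\].
#' @return the filtered `CoreMSRecords`.
#' @export
applyConfidenceFilter <- function(recs, minScore) {
  if (minScore < 0 || minScore > 1)
    stop("minScore must lie within [0, 1]")
  keep <- recs$Confidence >= minScore
  if (!any(keep))
    stop("confidence filter at ", minScore, " removes every record ",
         "(maximum score present: ", max(recs$Confidence), ")")
  .keepAttrs(as.data.frame(recs)[keep, , drop = FALSE], recs,
             step = list(step = "confidence_filter",
                         params = list(minScore = minScore),
                         rowsBefore = nrow(recs), rowsAfter = sum(keep),
                         timestamp = .timestamp()))
}

#' Resolve one molecular formula per (sample, m/z)
#'
#' Among candidate rows sharing a sample and m/z, keeps the one maximizing
#' the chosen criterion.  Ties are broken by smallest absolute mass error,
#' then by lexicographically smallest formula string, so output is
#' deterministic.
#'
#' @param recs a `CoreMSRecords` object.
#' @param method `"max_confidence"` (default) or `"max_peak_height"`.
#' @return `CoreMSRecords` with exactly one row per (sample, m/z).
#' @export
resolveFormulas <- function(recs,
                            method = c("max_confidence",
                                       "max_peak_height")) {
  method <- match.arg(method)
  crit <- if (method == "max_confidence") recs$Confidence else recs$Intensity
  err <- abs(recs$MassError)
  err[is.na(err)] <- Inf
  o <- order(recs$SampleID, recs$MZ, -crit, err, recs$Formula)
  df <- as.data.frame(recs)[o, , drop = FALSE]
  keep <- !duplicated(df[c("SampleID", "MZ")])
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  .keepAttrs(df, recs, resolved = TRUE,
             step = list(step = "resolve_formulas",
                         params = list(method = method),
                         rowsBefore = nrow(recs), rowsAfter = nrow(df),
                         timestamp = .timestamp()))
}

#' Pivot resolved CoreMS records into an FTMSExperiment
#'
#' Peaks are identified across samples by their resolved formula string
#' (isotope-annotated formulas are kept distinct); absent (sample, peak)
#' cells are missing.  The molecular table carries the formula, parsed
#' element counts, isotope annotation and the mean calibrated m/z as `Mass`.
#'
#' @param recs a resolved `CoreMSRecords` object (see [resolveFormulas()]).
#' @param strict passed to [parseMolecularFormula()].
#' @return an [FTMSExperiment-class] on the abundance scale with missing
#'   already encoded as `NA`.
#' @export
pivotToDataset <- function(recs, strict = TRUE) {
  if (!isTRUE(attr(recs, "resolved")) ||
      anyDuplicated(as.data.frame(recs)[c("SampleID", "MZ")]))
    stop("records carry multiple candidates per (sample, m/z); ",
         "run resolveFormulas first")
  df <- as.data.frame(recs)
  iso <- !is.na(df$Isotope) & nzchar(df$Isotope) & df$Isotope != "0" &
    df$Isotope != "FALSE"
  key <- ifelse(iso, paste0(df$Formula, " [", df$Isotope, "]"), df$Formula)
  samples <- unique(df$SampleID)
  peaks <- sort(unique(key))
  pt <- matrix(NA_real_, nrow = length(peaks), ncol = length(samples),
               dimnames = list(peaks, samples))
  dup <- duplicated(data.frame(key, df$SampleID))
  if (any(dup)) {
    warning(sum(dup), " record(s) resolved to a formula already present in ",
            "the same sample; keeping the first occurrence")
    df <- df[!dup, , drop = FALSE]
    key <- key[!dup]; iso <- iso[!dup]
  }
  pt[cbind(match(key, peaks), match(df$SampleID, samples))] <- df$Intensity
  first <- !duplicated(key)
  ord <- match(peaks, key[first])
  counts <- parseMolecularFormula(df$Formula[first][ord], strict = strict)
  mt <- data.frame(Formula = df$Formula[first][ord],
                   Isotope = df$Isotope[first][ord],
                   counts,
                   Mass = as.numeric(tapply(df$MZ, key, mean)[peaks]))
  ds <- FTMSExperiment(pt, mt, dataScale = "abundance", missingCode = 0,
                       missingEncoded = TRUE,
                       provenance = attr(recs, "provenance"))
  validObject(ds)
  .addStep(ds, "pivot_corems",
           params = list(samples = length(samples),
                         records = nrow(df)))
}
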