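#' Read the generalized two-file input
#'
#' Reads the "data file" (rows = masses, columns = samples, one mass
#' identifier column) and the "molecular identification file" (same masses,
#' with either a molecular formula string or element count columns
#' C,H,N,O,S,P; C and H are required) and returns a validated
#' [FTMSExperiment].
#'
#' Mass identifiers are read as character to avoid floating-point key drift.
#' When element count columns are absent they are parsed from the formula
#' column with [parseMolecularFormula()].
#'
#' @param dataFile path to the data file (CSV, header row required).
#' @param molidFile path to the molecular identification file (CSV).
#' @param massCol name of the mass identifier column, present in both files.
#' @param missingCode raw value denoting "not observed" (default 0).
#' @param dataScale scale of the intensities; one of `"abundance"`,
#'   `"log2"`, `"log10"`, `"ln"`, `"presence_absence"`.
#' @param formulaCol name of the formula column in `molidFile`; if `NULL`,
#'   auto-detected among common names (`Formula`, `MolForm`,
#'   `Molecular Formula`, `MolecularFormula`).
#' @param isotopeCol optional name of an isotope annotation column.
#' @param strict passed to [parseMolecularFormula()].
#' @return an [FTMSExperiment-class]; the upload parameters are recorded as
#'   the first provenance step.
#' @seealso [writeGeneralizedOutput()], [encodeMissing()]
#' @export
readGeneralizedInput <- function(dataFile, molidFile, massCol = "MassID",
                                 missingCode = 0, dataScale = "abundance",
                                 formulaCol = NULL, isotopeCol = NULL,
                                 strict = TRUE) {
  for (f in c(dataFile, molidFile))
    if (!file.exists(f)) stop("file not found: ", f)
  edata <- read.csv(dataFile, check.names = FALSE,
                    colClasses = setNames("character", massCol))
  emeta <- read.csv(molidFile, check.names = FALSE,
                    colClasses = setNames("character", massCol))
  for (nm in c("data file", "molecular identification file")) {
    df <- if (nm == "data file") edata else emeta
    if (!massCol %in% colnames(df))
      stop("mass identifier column '", massCol, "' not found in the ", nm)
    dup <- unique(df[[massCol]][duplicated(df[[massCol]])])
    if (length(dup))
      stop("duplicate mass identifiers in the ", nm, ": ",
           paste(head(dup, 5), collapse = ", "))
  }
  onlyE <- setdiff(edata[[massCol]], emeta[[massCol]])
  onlyM <- setdiff(emeta[[massCol]], edata[[massCol]])
  if (length(onlyE) || length(onlyM))
    stop("mass identifier sets differ between the two files; only in data ",
         "file: ", paste(head(onlyE, 5), collapse = ", "),
         "; only in molecular identification file: ",
         paste(head(onlyM, 5), collapse = ", "))

  ids <- edata[[massCol]]
  pt <- as.matrix(edata[setdiff(colnames(edata), massCol)])
  storage.mode(pt) <- "double"
  rownames(pt) <- ids

  emeta <- emeta[match(ids, emeta[[massCol]]), , drop = FALSE]
  mt <- emeta[setdiff(colnames(emeta), massCol)]
  rownames(mt) <- NULL
  if (is.null(formulaCol)) {
    cand <- c("Formula", "MolForm", "Molecular Formula", "MolecularFormula")
    formulaCol <- cand[cand %in% colnames(mt)][1]
    if (is.na(formulaCol)) formulaCol <- NULL
  } else if (!formulaCol %in% colnames(mt)) {
    stop("formula column '", formulaCol, "' not found in the molecular ",
         "identification file")
  }
  haveCounts <- all(c("C", "H") %in% colnames(mt))
  if (!haveCounts && is.null(formulaCol))
    stop("C and H are required: the molecular identification file must ",
         "contain either C and H count columns or a molecular formula column")
  if (haveCounts) {
    for (el in .ELEMENTS)
      if (el %in% colnames(mt)) mt[[el]] <- as.numeric(mt[[el]])
  } else {
    counts <- parseMolecularFormula(mt[[formulaCol]], strict = strict)
    mt <- cbind(mt, counts)
  }
  # an element column omitted from the file means "zero of that element"
  # for every peak that has a formula recorded
  for (el in .ELEMENTS)
    if (!el %in% colnames(mt)) mt[[el]] <- ifelse(is.na(mt$C), NA_real_, 0)
  if (!is.null(formulaCol) && formulaCol != "Formula") {
    mt$Formula <- mt[[formulaCol]]
  }
  if (!is.null(isotopeCol) && !isotopeCol %in% colnames(mt))
    stop("isotope column '", isotopeCol, "' not found in the molecular ",
         "identification file")
  # numeric mass for Kendrick/mass-range use, when the identifier parses
  if (!"Mass" %in% colnames(mt)) {
    m <- suppressWarnings(as.numeric(ids))
    if (!anyNA(m)) mt$Mass <- m
  }
  ds <- FTMSExperiment(pt, mt, dataScale = dataScale,
                       missingCode = missingCode)
  rownames(ds) <- ids
  validObject(ds)
  .addStep(ds, "upload",
           params = list(dataFile = basename(dataFile),
                         molidFile = basename(molidFile),
                         massCol = massCol, missingCode = missingCode,
                         dataScale = dataScale,
                         isotopeCol = isotopeCol))
}

#' Write an FTMSExperiment back to the generalized two-file format
#'
#' Inverse of [readGeneralizedInput()]: missing cells are written as the
#' dataset's `missingCode`, observed values verbatim; the molecular
#' identification file includes all calculated columns.
#'
#' @param ds an [FTMSExperiment-class].
#' @param dataFile,molidFile output CSV paths.
#' @param massCol name for the mass identifier column.
#' @return invisibly, the two paths.
#' @export
writeGeneralizedOutput <- function(ds, dataFile, molidFile,
                                   massCol = "MassID") {
  pt <- peakTable(ds)
  pt[is.na(pt)] <- missingCode(ds)
  edata <- data.frame(check.names = FALSE,
                      setNames(list(rownames(ds)), massCol), pt)
  emeta <- data.frame(check.names = FALSE,
                      setNames(list(rownames(ds)), massCol),
                      as.data.frame(molTable(ds)))
  write.csv(edata, dataFile, row.names = FALSE)
  write.csv(emeta, molidFile, row.names = FALSE)
  invisible(c(dataFile, molidFile))
}

#' Encode missing values
#'
#' Replaces every cell equal to the dataset's `missingCode` with `NA`, the
#' canonical missing marker, so that observed counts and presence/absence
#' are unambiguous.  Idempotent.
#'
#' @param ds an [FTMSExperiment-class].
#' @return the dataset with missing cells set to `NA` and
#'   `isMissingEncoded(ds) == TRUE`.
#' @export
encodeMissing <- function(ds) {
  pt <- assay(ds, "intensity")
  pt[!is.na(pt) & pt == missingCode(ds)] <- NA_real_
  assay(ds, "intensity") <- pt
  ds@missingEncoded <- TRUE
  .addStep(ds, "encode_missing",
           params = list(missingCode = missingCode(ds)))
}

#' Transform the intensity scale
#'
#' Log transforms (`log2`, `log10`, `ln`) require the current scale to be
#' `abundance` (no double-logging) and strictly positive observed values;
#' `presence_absence` maps observed cells to 1 and missing cells to 0 on any
#' scale.  Missing stays missing under log transforms.
#'
#' @param ds an [FTMSExperiment-class] with missing encoded.
#' @param target one of `"log2"`, `"log10"`, `"ln"`, `"presence_absence"`,
#'   `"abundance"` (identity).
#' @return the transformed dataset with `dataScale` updated.
#' @export
transformScale <- function(ds,
                           target = c("log2", "log10", "ln",
                                      "presence_absence", "abundance")) {
  target <- match.arg(target)
  if (!isMissingEncoded(ds))
    stop("encode missing values first (encodeMissing) so observed and ",
         "missing cells cannot be conflated")
  cur <- dataScale(ds)
  if (target == cur) return(.addStep(ds, "transform_scale",
                                     params = list(target = target)))
  pt <- assay(ds, "intensity")
  if (target == "presence_absence") {
    pt <- ifelse(is.na(pt), 0, 1)
  } else if (target == "abundance") {
    stop("cannot transform '", cur, "' data back to abundance")
  } else {
    if (cur != "abundance")
      stop("log transform requires abundance-scale data; current scale is '",
           cur, "' (no double-logging)")
    obs <- !is.na(pt)
    if (any(pt[obs] <= 0))
      stop("log transform of non-positive observed values; if these encode ",
           "missingness, set missingCode accordingly and re-encode")
    fn <- switch(target, log2 = log2, log10 = log10, ln = log)
    pt[obs] <- fn(pt[obs])
  }
  assay(ds, "intensity") <- pt
  ds@dataScale <- target
  .addStep(ds, "transform_scale", params = list(target = target))
}

#' Remove isotope-flagged peaks
#'
#' Drops peaks whose isotope annotation equals `isotopeValue` from both the
#' peak table and the molecular table.
#'
#' @param ds an [FTMSExperiment-class].
#' @param isotopeCol name of the isotope column in the molecular table.
#' @param isotopeValue value flagging an isotopic peak (e.g. `"C13"` or 1).
#' @return the dataset without isotopic peaks.
#' @export
filterIsotopes <- function(ds, isotopeCol = "Isotope", isotopeValue = 1) {
  rd <- molTable(ds)
  if (!isotopeCol %in% colnames(rd))
    stop("isotope column '", isotopeCol, "' not found in the molecular table")
  flag <- rd[[isotopeCol]]
  drop <- !is.na(flag) & flag == isotopeValue
  if (all(drop))
    stop("empty dataset after filter: every peak is flagged as isotopic")
  before <- dim(ds)
  out <- ds[!drop, ]
  .addStep(out, "filter_isotopes",
           params = list(isotopeCol = isotopeCol,
                         isotopeValue = isotopeValue,
                         removed = sum(drop)),
           before = before, after = dim(out))
}

#' Detect sample groups from sample names
#'
#' Assigns each sample whose name contains a pattern (plain substring match
#' by default, case-sensitive) to that pattern's group; patterns are tried
#' in order and the first match wins.
#'
#' @param sampleNames character vector of sample names.
#' @param patterns character vector of patterns; its `names` (or the
#'   `labels` argument) give the group labels.
#' @param labels group labels parallel to `patterns`; defaults to
#'   `names(patterns)`, or to the patterns themselves.
#' @param regex if `TRUE` patterns are interpreted as regular expressions
#'   instead of fixed substrings.
#' @return named character vector mapping each matched sample name to its
#'   group label (unmatched samples are omitted); empty, with a warning,
#'   when nothing matches.
#' @examples
#' detectGroups(c("A_d01_r1", "A_d04_r1"),
#'              c(Depth0.1 = "d01", Depth0.4 = "d04"))
#' @export
detectGroups <- function(sampleNames, patterns, labels = NULL,
                         regex = FALSE) {
  if (length(patterns) == 0L) stop("patterns must be non-empty")
  if (any(!nzchar(patterns))) stop("empty pattern")
  if (is.null(labels))
    labels <- if (!is.null(names(patterns))) names(patterns) else
      as.character(patterns)
  if (length(labels) != length(patterns))
    stop("labels must be parallel to patterns")
  assign <- rep(NA_character_, length(sampleNames))
  for (i in seq_along(patterns)) {
    hit <- grepl(patterns[[i]], sampleNames, fixed = !regex)
    assign[is.na(assign) & hit] <- labels[[i]]
  }
  matched <- !is.na(assign)
  if (!any(matched)) {
    warning("no sample name matched any pattern")
    return(setNames(character(0), character(0)))
  }
  setNames(assign[matched], sampleNames[matched])
}

#' Per-sample summary of observed peaks
#'
#' For each sample: the number of observed (non-missing) peaks and the
#' five-number summary (min, lower quartile, median, upper quartile, max) of
#' the observed intensities — the statistics behind the QC boxplots.
#'
#' @param ds an [FTMSExperiment-class] with missing encoded.
#' @return data.frame with columns `Sample`, `ObservedPeaks`, `Min`, `Q1`,
#'   `Median`, `Q3`, `Max` (quantiles `NA` for an all-missing sample).
#' @export
summarizeDataset <- function(ds) {
  if (!isMissingEncoded(ds))
    stop("encode missing values first (encodeMissing)")
  pt <- peakTable(ds)
  res <- lapply(seq_len(ncol(pt)), function(j) {
    v <- pt[, j]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      return(data.frame(Sample = colnames(pt)[j], ObservedPeaks = 0L,
                        Min = NA_real_, Q1 = NA_real_, Median = NA_real_,
                        Q3 = NA_real_, Max = NA_real_))
    q <- unname(quantile(v, c(0, 0.25, 0.5, 0.75, 1)))
    data.frame(Sample = colnames(pt)[j], ObservedPeaks = length(v),
               Min = q[1], Q1 = q[2], Median = q[3], Q3 = q[4], Max = q[5])
  })
  do.call(rbind, res)
}
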