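# Sequential peak/sample filters with retention accounting.  Each filter's
# membership (which peaks/samples it keeps) is computed against the dataset
# as passed to applyFilters(), and the chain is applied as a running set
# intersection: retention counts depend on the order (the bar-chart view of
# "each filter applied sequentially"), the final peak set does not.

.newFilter <- function(kind, ...) {
  structure(list(kind = kind, ...), class = c(paste0(kind, "Filter"),
                                              "FilterSpec"))
}

#' Filter specifications
#'
#' Constructors for the predefined filters and for custom filters on
#' molecular-table columns.  Pass an ordered list of specs to
#' [applyFilters()].
#'
#' * `massFilter(min, max)` keeps peaks whose numeric mass lies in
#'   `[min, max]` (inclusive).
#' * `minObservedFilter(minCount, perGroup)` keeps peaks observed (non
#'   missing) in at least `minCount` samples; with `perGroup = TRUE` a peak
#'   is kept if ANY group meets the minimum.
#' * `formulaFilter()` keeps peaks with an assigned molecular formula.
#' * `sampleNameFilter(keep, remove)` keeps/removes sample columns by name;
#'   peak-level retention is unchanged by this step.
#' * `customFilter(column, min, max, values)` keeps peaks whose value in a
#'   molecular-table column (including calculated columns) lies in the
#'   inclusive numeric range `[min, max]`, or belongs to the `values` set
#'   for categorical columns.
#'
#' @param min,max inclusive numeric bounds (`massFilter`: both required and
#'   `min < max`; `customFilter`: either may be `NULL` for one-sided).
#' @param minCount minimum number of non-missing observations (>= 1).
#' @param perGroup apply the minimum within groups (ANY group qualifies).
#' @param keep,remove character vectors of sample names (exactly one of the
#'   two for `sampleNameFilter`).
#' @param column molecular-table column name for `customFilter`.
#' @param values keep-set for a categorical `customFilter`.
#' @return a `FilterSpec` object.
#' @name FilterSpec
NULL

#' @rdname FilterSpec
#' @export
massFilter <- function(min, max) {
  if (!is.numeric(min) || !is.numeric(max) || min >= max)
    stop("massFilter requires numeric bounds with min < max")
  .newFilter("mass", min = min, max = max)
}

#' @rdname FilterSpec
#' @export
minObservedFilter <- function(minCount = 2, perGroup = FALSE) {
  if (minCount < 1) stop("minCount must be at least 1")
  .newFilter("minObserved", minCount = minCount, perGroup = perGroup)
}

#' @rdname FilterSpec
#' @export
formulaFilter <- function() .newFilter("formula")

#' @rdname FilterSpec
#' @export
sampleNameFilter <- function(keep = NULL, remove = NULL) {
  if (is.null(keep) == is.null(remove))
    stop("supply exactly one of keep or remove")
  .newFilter("sampleName", keep = keep, remove = remove)
}

#' @rdname FilterSpec
#' @export
customFilter <- function(column, min = NULL, max = NULL, values = NULL) {
  if (is.null(values) && is.null(min) && is.null(max))
    stop("customFilter needs a numeric range (min/max) or a values set")
  .newFilter("custom", column = column, min = min, max = max,
             values = values)
}

#' @export
print.FilterSpec <- function(x, ...) {
  cat(.filterName(x), "\n")
  invisible(x)
}

.filterName <- function(f) {
  switch(f$kind,
    mass = sprintf("mass range [%g, %g]", f$min, f$max),
    minObserved = sprintf("minimum %d observed%s", f$minCount,
                          if (isTRUE(f$perGroup)) " (per group)" else ""),
    formula = "molecular formula assigned",
    sampleName = if (!is.null(f$keep))
      sprintf("keep samples: %s", paste(f$keep, collapse = ", "))
    else sprintf("remove samples: %s", paste(f$remove, collapse = ", ")),
    custom = sprintf("custom on %s", f$column))
}

# membership of one filter evaluated on `ds` (the chain input); returns
# list(peaks = logical over rows, samples = logical over columns)
.filterMembership <- function(ds, f, groupVec) {
  peaks <- rep(TRUE, nrow(ds))
  samples <- rep(TRUE, ncol(ds))
  rd <- molTable(ds)
  if (f$kind == "mass") {
    mass <- rd$Mass
    if (is.null(mass)) mass <- suppressWarnings(as.numeric(rownames(ds)))
    if (all(is.na(mass)))
      stop("mass filter needs a numeric 'Mass' column or numeric mass ",
           "identifiers")
    peaks <- !is.na(mass) & mass >= f$min & mass <= f$max
  } else if (f$kind == "minObserved") {
    if (!isMissingEncoded(ds))
      stop("encode missing values first (encodeMissing)")
    obs <- !is.na(peakTable(ds))
    if (isTRUE(f$perGroup)) {
      if (is.null(groupVec) || all(is.na(groupVec)))
        stop("per-group minimum-observed filter requires group assignments")
      labs <- unique(groupVec[!is.na(groupVec)])
      perG <- vapply(labs, function(g)
        rowSums(obs[, !is.na(groupVec) & groupVec == g, drop = FALSE]),
        numeric(nrow(ds)))
      peaks <- apply(perG >= f$minCount, 1L, any)
    } else {
      peaks <- rowSums(obs) >= f$minCount
    }
  } else if (f$kind == "formula") {
    peaks <- !is.na(rd$C)
  } else if (f$kind == "sampleName") {
    nm <- colnames(ds)
    tgt <- if (!is.null(f$keep)) f$keep else f$remove
    unknown <- setdiff(tgt, nm)
    if (length(unknown))
      stop("sample name filter refers to unknown sample(s): ",
           paste(unknown, collapse = ", "))
    samples <- if (!is.null(f$keep)) nm %in% f$keep else !(nm %in% f$remove)
  } else if (f$kind == "custom") {
    if (!f$column %in% colnames(rd))
      stop("custom filter column '", f$column, "' not found in the ",
           "molecular table or calculated columns")
    v <- rd[[f$column]]
    if (!is.null(f$values)) {
      peaks <- !is.na(v) & v %in% f$values
    } else {
      peaks <- !is.na(v)
      if (!is.null(f$min)) peaks <- peaks & v >= f$min
      if (!is.null(f$max)) peaks <- peaks & v <= f$max
    }
  } else stop("unknown filter kind: ", f$kind)
  list(peaks = peaks, samples = samples)
}

#' Apply an ordered chain of filters
#'
#' Applies the filters sequentially and records, for the filter bar chart,
#' the number of peaks before and after each step and how many of the
#' retained peaks carry a formula.  Each filter's membership is evaluated
#' against the input dataset, so the final peak set is invariant under
#' reordering of the chain while the per-step counts reflect the order
#' given.  The pre-filter dataset is retained (in
#' `metadata(ds)$unfiltered`) for [resetFilters()].
#'
#' @param ds an [FTMSExperiment-class].
#' @param filters list of [FilterSpec] objects, applied in order.
#' @param groups optional named group vector (see [groups()]); defaults to
#'   `groups(ds)`.  Needed for per-group minimum-observed filters.
#' @return the filtered dataset; the retention table is available via
#'   [filterRetention()].
#' @examples
#' \dontrun{
#' ds2 <- applyFilters(ds, list(massFilter(200, 900),
#'                              minObservedFilter(2), formulaFilter()))
#' filterRetention(ds2)
#' }
#' @export
applyFilters <- function(ds, filters, groups = NULL) {
  if (inherits(filters, "FilterSpec")) filters <- list(filters)
  stopifnot(all(vapply(filters, inherits, TRUE, "FilterSpec")))
  if (is.null(groups)) {
    gv <- colData(ds)$Group
  } else {
    tmp <- ds; groups(tmp) <- groups
    gv <- colData(tmp)$Group
  }
  if (is.null(metadata(ds)$unfiltered)) {
    snap <- ds
    metadata(snap)$unfiltered <- NULL
    metadata(ds)$unfiltered <- snap
  }
  keepPeaks <- rep(TRUE, nrow(ds))
  keepSamples <- rep(TRUE, ncol(ds))
  hasFormula <- !is.na(molTable(ds)$C)
  retention <- data.frame(Filter = character(), PeaksBefore = integer(),
                          PeaksAfter = integer(),
                          FormulaAfter = integer())
  out <- ds
  for (f in filters) {
    m <- .filterMembership(ds, f, gv)
    before <- sum(keepPeaks)
    keepPeaks <- keepPeaks & m$peaks
    keepSamples <- keepSamples & m$samples
    after <- sum(keepPeaks)
    if (after == 0L)
      stop("empty dataset after filter: ", .filterName(f))
    if (!any(keepSamples))
      stop("no samples left after filter: ", .filterName(f))
    retention <- rbind(retention, data.frame(
      Filter = .filterName(f), PeaksBefore = before, PeaksAfter = after,
      FormulaAfter = sum(keepPeaks & hasFormula)))
    out <- .addStep(out, "filter", params = list(filter = .filterName(f)),
                    before = c(before, ncol(ds)),
                    after = c(after, sum(keepSamples)))
  }
  prov <- out@provenance
  out <- out[keepPeaks, keepSamples]
  out@provenance <- prov
  md <- metadata(out)
  md$filterRetention <- rbind(md$filterRetention, retention)
  metadata(out) <- md
  out
}

#' @describeIn applyFilters the retention table (one row per filter step:
#'   `Filter`, `PeaksBefore`, `PeaksAfter`, `FormulaAfter`), or `NULL` when
#'   no filters have been applied.
#' @export
filterRetention <- function(ds) metadata(ds)$filterRetention

#' Reset all filters
#'
#' Returns the dataset as it was before the first [applyFilters()] call
#' (preprocessing columns computed before filtering are retained); records
#' the reset in provenance.
#'
#' @param ds an [FTMSExperiment-class].
#' @return the pre-filter dataset.
#' @export
resetFilters <- function(ds) {
  orig <- metadata(ds)$unfiltered
  if (is.null(orig)) orig <- ds
  prov <- c(ds@provenance,
            list(list(step = "reset_filters", params = list(),
                      peaksBefore = nrow(ds), peaksAfter = nrow(orig),
                      samplesBefore = ncol(ds), samplesAfter = ncol(orig),
                      timestamp = .timestamp())))
  orig@provenance <- prov
  metadata(orig)$filterRetention <- NULL
  orig
}
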