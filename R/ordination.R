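# Sample ordination (PCoA / classical multidimensional scaling) and the
# plot-ready tables behind van Krevelen, Kendrick, density, scatter and QC
# displays.  Tables are plain data.frames with "kind" and axis-label
# attributes; rendering is left to the caller.

#' Pairwise sample distances
#'
#' For the abundance metrics (`euclidean`, `manhattan`, `bray_curtis`)
#' missing cells are treated as zero abundance; `jaccard_presence` is
#' computed on presence/absence (a peak is present where its intensity is
#' observed).
#'
#' @param ds an [FTMSExperiment-class] with missing encoded; at least two
#'   samples.
#' @param metric one of `"euclidean"`, `"manhattan"`, `"bray_curtis"`,
#'   `"jaccard_presence"`.
#' @return symmetric distance matrix with sample names, zero diagonal; the
#'   metric is recorded in `attr(, "metric")`.
#' @export
distanceMatrix <- function(ds,
                           metric = c("euclidean", "manhattan",
                                      "bray_curtis", "jaccard_presence")) {
  metric <- match.arg(metric)
  if (!isMissingEncoded(ds))
    stop("encode missing values first (encodeMissing)")
  if (ncol(ds) < 2L) stop("at least two samples are required")
  pt <- peakTable(ds)
  d <- switch(metric,
    euclidean = ,
    manhattan = {
      m <- t(pt); m[is.na(m)] <- 0
      dist(m, method = metric)
    },
    bray_curtis = {
      m <- t(pt); m[is.na(m)] <- 0
      vegan::vegdist(m, method = "bray")
    },
    jaccard_presence =
      vegan::vegdist(t(!is.na(pt)) * 1, method = "jaccard", binary = TRUE))
  dm <- as.matrix(d)
  dimnames(dm) <- list(colnames(ds), colnames(ds))
  attr(dm, "metric") <- metric
  dm
}

#' Principal coordinate analysis
#'
#' Classical scaling of a distance matrix: eigendecomposition of the
#' double-centered matrix of negative half squared distances.  Up to five
#' axes with positive eigenvalues are returned; negative eigenvalues (which
#' arise for non-euclidean metrics) are dropped from the coordinates and
#' from the variance-explained denominator, so `R2[i]` is eigenvalue `i`
#' over the sum of positive eigenvalues.
#'
#' @param d distance matrix (or `dist`) — square, symmetric, zero diagonal.
#' @param k maximum number of axes (default 5).
#' @return an object of class `PCoAResult`: list with `coordinates`
#'   (samples x axes), `eigenvalues` (all), `R2` (per returned axis),
#'   `metric`.
#' @export
runPCoA <- function(d, k = 5) {
  metric <- attr(d, "metric")
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8) ||
      any(abs(diag(dm)) > 1e-12))
    stop("d must be a symmetric distance matrix with a zero diagonal")
  n <- nrow(dm)
  fit <- cmdscale(stats::as.dist(dm), k = min(k, n - 1L), eig = TRUE)
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-8
  pos <- eig > tol
  if (!any(pos)) stop("no positive eigenvalues; degenerate distance matrix")
  naxes <- min(k, sum(pos), ncol(fit$points))
  coords <- fit$points[, seq_len(naxes), drop = FALSE]
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("Axis", seq_len(naxes))
  r2 <- eig[seq_len(naxes)] / sum(eig[pos])
  structure(list(coordinates = coords, eigenvalues = eig, R2 = r2,
                 metric = if (is.null(metric)) NA_character_ else metric),
            class = "PCoAResult")
}

#' @export
print.PCoAResult <- function(x, ...) {
  cat("PCoA (", x$metric, "): ", nrow(x$coordinates), " samples, ",
      ncol(x$coordinates), " axes\n", sep = "")
  cat("  R2:", paste(sprintf("%.3f", x$R2), collapse = ", "), "\n")
  invisible(x)
}

.plotTable <- function(df, kind, xlab, ylab, colorBy = NULL) {
  rownames(df) <- NULL
  attr(df, "kind") <- kind
  attr(df, "xlab") <- xlab
  attr(df, "ylab") <- ylab
  attr(df, "colorBy") <- colorBy
  df
}

.colorColumn <- function(rd, colorBy) {
  if (is.null(colorBy)) return(NULL)
  if (!colorBy %in% colnames(rd))
    stop("unknown color column: ", colorBy)
  rd[[colorBy]]
}

.attachUniqueness <- function(df, comparison, ids) {
  if (is.null(comparison)) return(df)
  df$uniqueness <- as.character(comparison[ids, "uniqueness"])
  df
}

#' Van Krevelen plot table
#'
#' One point per peak with computed elemental ratios: x = O:C, y = H:C,
#' with formula and mass carried as hover fields.  When a comparison result
#' is supplied its uniqueness label is attached (rows labeled
#' `observed_in_both` included; subset downstream to toggle them off).
#'
#' @param ds an [FTMSExperiment-class] after [calculateProperties()].
#' @param colorBy optional molecular-table column supplying color values.
#' @param comparison optional `DataFrame` from [thresholdUniqueness()] /
#'   [gtestUniqueness()].
#' @return data.frame with columns `massId`, `x`, `y`, `Formula`, `Mass`
#'   (+ `color`, `uniqueness`); plot metadata in attributes `kind`,
#'   `xlab`, `ylab`.
#' @export
vanKrevelenTable <- function(ds, colorBy = NULL, comparison = NULL) {
  rd <- molTable(ds)
  if (!all(c("OtoC", "HtoC") %in% colnames(rd)))
    stop("elemental ratios not computed; run calculateProperties(ds, ",
         "'ratios') first")
  keep <- is.finite(rd$OtoC) & is.finite(rd$HtoC)
  df <- data.frame(massId = rownames(ds)[keep],
                   x = rd$OtoC[keep], y = rd$HtoC[keep],
                   Formula = if ("Formula" %in% colnames(rd))
                     rd$Formula[keep] else NA_character_,
                   Mass = if ("Mass" %in% colnames(rd)) rd$Mass[keep]
                   else suppressWarnings(as.numeric(rownames(ds)[keep])))
  cv <- .colorColumn(rd, colorBy)
  if (!is.null(cv)) df$color <- cv[keep]
  df <- .attachUniqueness(df, comparison, df$massId)
  .plotTable(df, "van_krevelen", "O:C", "H:C", colorBy)
}

#' Kendrick plot table
#'
#' x = Kendrick mass, y = Kendrick defect, for peaks where both were
#' computed.
#'
#' @inheritParams vanKrevelenTable
#' @return data.frame as in [vanKrevelenTable()].
#' @export
kendrickTable <- function(ds, colorBy = NULL, comparison = NULL) {
  rd <- molTable(ds)
  if (!all(c("KendrickMass", "KendrickDefect") %in% colnames(rd)))
    stop("Kendrick mass/defect not computed; run calculateProperties(ds, ",
         "'kendrick') first")
  keep <- is.finite(rd$KendrickMass) & is.finite(rd$KendrickDefect)
  df <- data.frame(massId = rownames(ds)[keep],
                   x = rd$KendrickMass[keep], y = rd$KendrickDefect[keep],
                   Formula = if ("Formula" %in% colnames(rd))
                     rd$Formula[keep] else NA_character_,
                   Mass = if ("Mass" %in% colnames(rd)) rd$Mass[keep]
                   else suppressWarnings(as.numeric(rownames(ds)[keep])))
  cv <- .colorColumn(rd, colorBy)
  if (!is.null(cv)) df$color <- cv[keep]
  df <- .attachUniqueness(df, comparison, df$massId)
  .plotTable(df, "kendrick", "Kendrick mass", "Kendrick defect", colorBy)
}

#' Custom scatter plot table
#'
#' Points for peaks carrying values in both chosen molecular-table columns.
#'
#' @inheritParams vanKrevelenTable
#' @param x,y molecular-table column names.
#' @return data.frame with `massId`, `x`, `y` (+ `color`).
#' @export
scatterTable <- function(ds, x, y, colorBy = NULL) {
  rd <- molTable(ds)
  for (col in c(x, y))
    if (!col %in% colnames(rd)) stop("unknown column: ", col)
  xv <- rd[[x]]; yv <- rd[[y]]
  keep <- !is.na(xv) & !is.na(yv)
  if (is.numeric(xv)) keep <- keep & is.finite(xv)
  if (is.numeric(yv)) keep <- keep & is.finite(yv)
  df <- data.frame(massId = rownames(ds)[keep], x = xv[keep], y = yv[keep])
  cv <- .colorColumn(rd, colorBy)
  if (!is.null(cv)) df$color <- cv[keep]
  .plotTable(df, "scatter", x, y, colorBy)
}

#' Density plot table
#'
#' Kernel-density curves (Gaussian kernel, Silverman's rule-of-thumb
#' bandwidth) of a calculated property over the peaks observed in each
#' sample (or pooled per group), all evaluated on one shared 512-point grid
#' so curves are directly comparable.  The grid spans the pooled value
#' range extended by four bandwidths.  Units with fewer than two distinct
#' values are omitted with a warning.
#'
#' @param ds an [FTMSExperiment-class] with missing encoded.
#' @param variable numeric molecular-table column.
#' @param by `"sample"` (one curve per sample) or `"group"` (values pooled
#'   over each group's samples).
#' @param groups named group vector (needed for `by = "group"`); defaults
#'   to `groups(ds)`.
#' @param includeCombined add a pooled `"combined"` curve over all units.
#' @param gridSize number of grid points (default 512).
#' @return long data.frame with columns `unit`, `x`, `density`.
#' @export
densityTable <- function(ds, variable, by = c("sample", "group"),
                         groups = NULL, includeCombined = FALSE,
                         gridSize = 512) {
  by <- match.arg(by)
  if (!isMissingEncoded(ds))
    stop("encode missing values first (encodeMissing)")
  rd <- molTable(ds)
  if (!variable %in% colnames(rd)) stop("unknown column: ", variable)
  v <- rd[[variable]]
  if (!is.numeric(v)) stop("variable must be numeric: ", variable)
  obs <- !is.na(peakTable(ds))
  if (by == "sample") {
    units <- setNames(lapply(colnames(ds), function(s) {
      x <- v[obs[, s]]; x[!is.na(x)]
    }), colnames(ds))
  } else {
    if (is.null(groups)) g <- groups(ds)
    else { tmp <- ds; groups(tmp) <- groups; g <- groups(tmp) }
    g <- g[!is.na(g)]
    if (!length(g)) stop("by = 'group' requires group assignments")
    # each observation is a peak observed in one of the group's samples
    units <- lapply(split(names(g), g), function(ss) {
      x <- unlist(lapply(ss, function(s) v[obs[, s]]), use.names = FALSE)
      x[!is.na(x)]
    })
  }
  if (includeCombined)
    units <- c(units, list(combined = unlist(units, use.names = FALSE)))
  usable <- vapply(units, function(x) length(unique(x)) >= 2L, TRUE)
  if (any(!usable))
    warning("omitting unit(s) with fewer than two distinct values: ",
            paste(names(units)[!usable], collapse = ", "))
  units <- units[usable]
  if (!length(units)) stop("no unit has enough values for a density curve")
  pooled <- unlist(units, use.names = FALSE)
  bws <- vapply(units, bw.nrd0, 0)
  pad <- 4 * max(bws)
  grid <- seq(min(pooled) - pad, max(pooled) + pad, length.out = gridSize)
  out <- do.call(rbind, lapply(names(units), function(u) {
    den <- density(units[[u]], bw = bws[[u]], from = grid[1L],
                   to = grid[gridSize], n = gridSize)
    data.frame(unit = u, x = den$x, density = den$y)
  }))
  .plotTable(out, "density", variable, "density")
}

#' Quality-control tables
#'
#' Per-sample five-number summaries of the observed intensities (boxplot
#' statistics) and observed-peak counts (bar chart), optionally on another
#' scale and restricted to samples of given groups.
#'
#' @param ds an [FTMSExperiment-class] with missing encoded.
#' @param groups optional named group vector; when supplied together with
#'   `groupFilter`, only samples of those groups are reported.
#' @param groupFilter character vector of group labels to keep.
#' @param scale optional target scale (see [transformScale()]); applied on
#'   the fly from abundance data.
#' @return list with elements `boxplot` (per-sample `Sample`, `Group`,
#'   `ObservedPeaks`, `Min`, `Q1`, `Median`, `Q3`, `Max`) and `counts`
#'   (`Sample`, `Group`, `ObservedPeaks`).
#' @export
qcTables <- function(ds, groups = NULL, groupFilter = NULL, scale = NULL) {
  if (!is.null(groups)) groups(ds) <- groups
  g <- groups(ds)
  if (!is.null(groupFilter)) {
    keep <- !is.na(g) & g %in% groupFilter
    if (!any(keep)) stop("no sample belongs to the requested group(s)")
    ds <- ds[, keep]
    g <- g[keep]
  }
  if (!is.null(scale) && scale != dataScale(ds))
    ds <- transformScale(ds, scale)
  sm <- summarizeDataset(ds)
  sm$Group <- unname(g[sm$Sample])
  sm <- sm[c("Sample", "Group", "ObservedPeaks", "Min", "Q1", "Median",
             "Q3", "Max")]
  list(boxplot = sm,
       counts = sm[c("Sample", "Group", "ObservedPeaks")])
}
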