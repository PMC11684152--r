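# Provenance report: a self-contained HTML document assembled from an
# internal markdown-like template.  Equations are rendered as plain text so
# the report has no external dependencies; with a pinned timestamp (option
# "ftmseda.timestamp") two identical runs give byte-identical files.

# plain-text equations shown for each calculated property family
.PROPERTY_EQUATIONS <- c(
  OtoC = "O:C = O / C",
  HtoC = "H:C = H / C",
  NtoC = "N:C = N / C",
  PtoC = "P:C = P / C",
  NtoP = "N:P = N / P (P >= 1)",
  KendrickMass = "KM = mass * 14 / 14.01565",
  KendrickDefect = "KMD = ceiling(KM) - KM",
  NOSC = "NOSC = 4 - (4C + H - 3N - 2O - 2S + 5P) / C",
  GFE = "GFE = 60.3 - 28.5 * NOSC  [kJ per mol C]",
  AI = "AI = (1 + C - O - S - 0.5H) / (C - O - S - N - P), clamped to 0",
  AImod = "AImod = AI with O replaced by 0.5 O",
  DBE = "DBE = 1 + (2C - H + N + P) / 2",
  ElComposition = "symbols with non-zero count, order C,H,N,O,S,P",
  CompoundClass = "van Krevelen (O:C, H:C) boundary-set lookup")

.esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.htmlTable <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return("<p>(none)</p>")
  fmt <- function(v) if (is.numeric(v)) format(v, digits = 6) else
    as.character(v)
  cells <- vapply(df, fmt, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  head <- paste0("<tr>", paste0("<th>", .esc(colnames(df)), "</th>",
                                collapse = ""), "</tr>")
  rows <- apply(cells, 1L, function(r)
    paste0("<tr>", paste0("<td>", .esc(r), "</td>", collapse = ""),
           "</tr>"))
  paste0("<table border='1' cellpadding='4' cellspacing='0'>", head,
         paste(rows, collapse = ""), "</table>")
}

.describeParams <- function(p) {
  if (!length(p)) return("")
  paste(vapply(names(p), function(k)
    paste0(k, " = ", paste(format(unlist(p[[k]])), collapse = ",")), ""),
    collapse = "; ")
}

#' Generate the provenance report
#'
#' Writes a self-contained HTML summary: input dimensions and upload
#' selections, every calculated property present with its equation, every
#' filter with before/after peak counts, the full provenance trail, and a
#' summary of any group comparison (method, settings, label counts).
#' Deterministic given identical provenance when the option
#' `ftmseda.timestamp` pins the report timestamp.
#'
#' @param ds an [FTMSExperiment-class] with non-empty provenance.
#' @param comparisons optional named list of comparison results
#'   ([thresholdUniqueness()] / [gtestUniqueness()]).
#' @param file output HTML path.
#' @return invisibly, the HTML string (also written to `file`).
#' @export
generateReport <- function(ds, comparisons = NULL, file) {
  prov <- provenance(ds)
  if (!length(prov)) stop("provenance is empty; nothing to report")
  rd <- molTable(ds)
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>FT-MS analysis report</title></head><body>",
    "<h1>FT-MS exploratory analysis report</h1>",
    paste0("<p>Generated: ", .esc(.timestamp()), "</p>"),
    "<h2>Dataset</h2>",
    paste0("<p>", nrow(ds), " peaks x ", ncol(ds), " samples; scale: ",
           dataScale(ds), "; missing code: ", missingCode(ds),
           "; peaks with formula: ", sum(!is.na(rd$C)), ".</p>"))
  up <- Filter(function(s) s$step == "upload", prov)
  if (length(up))
    parts <- c(parts, "<h2>Upload selections</h2>",
               paste0("<p>", .esc(.describeParams(up[[1L]]$params)),
                      "</p>"))
  calc <- intersect(names(.PROPERTY_EQUATIONS), colnames(rd))
  if (length(calc)) {
    eq <- data.frame(Property = calc,
                     Equation = unname(.PROPERTY_EQUATIONS[calc]))
    parts <- c(parts, "<h2>Calculated properties</h2>", .htmlTable(eq))
  }
  filt <- Filter(function(s) s$step %in% c("filter", "filter_isotopes"),
                 prov)
  if (length(filt)) {
    ft <- do.call(rbind, lapply(filt, function(s) data.frame(
      Filter = if (s$step == "filter_isotopes") "isotope filter"
      else .describeParams(s$params),
      PeaksBefore = s$peaksBefore, PeaksAfter = s$peaksAfter)))
    parts <- c(parts, "<h2>Filters applied</h2>", .htmlTable(ft))
  }
  if (!is.null(comparisons)) {
    if (!is.list(comparisons) || inherits(comparisons, "DataFrame"))
      comparisons <- list(comparison = comparisons)
    parts <- c(parts, "<h2>Group comparisons</h2>")
    for (nm in names(comparisons)) {
      cmp <- comparisons[[nm]]
      md <- metadata(cmp)
      cnt <- table(cmp$uniqueness)
      parts <- c(parts,
        paste0("<h3>", .esc(nm), "</h3>"),
        paste0("<p>Method: ", md$method, "; groups: ",
               paste(md$groupLabels, collapse = " vs "), " (n = ",
               paste(md$groupSizes, collapse = ", "), "); settings: ",
               .esc(.describeParams(md$config)), "</p>"),
        .htmlTable(data.frame(Label = names(cnt),
                              Peaks = as.integer(cnt))))
    }
  }
  steps <- do.call(rbind, lapply(prov, function(s) data.frame(
    Step = s$step, Parameters = .describeParams(s$params),
    PeaksBefore = s$peaksBefore, PeaksAfter = s$peaksAfter,
    Timestamp = s$timestamp)))
  parts <- c(parts, "<h2>Provenance</h2>", .htmlTable(steps),
             "</body></html>")
  html <- paste(parts, collapse = "\n")
  writeLines(html, file)
  invisible(html)
}

#' Export the processed data, results and report as a CSV bundle
#'
#' Writes to `dir`: the processed data file and molecular identification
#' file (round-trippable through [readGeneralizedInput()]), optionally a
#' merged sheet (join on mass identifier), per-group summary and
#' uniqueness-test CSVs when comparisons are supplied, any plot tables, and
#' the HTML report.
#'
#' @param ds an [FTMSExperiment-class].
#' @param dir output directory (created if needed).
#' @param comparisons optional named list of comparison results.
#' @param plots optional named list of plot tables.
#' @param merged also write the merged data + molecular sheet.
#' @param report write `report.html` via [generateReport()].
#' @param massCol mass identifier column name used in the CSVs.
#' @return invisibly, a named character vector of the files written.
#' @export
exportBundle <- function(ds, dir, comparisons = NULL, plots = NULL,
                         merged = FALSE, report = TRUE, massCol = "MassID") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- c(data = file.path(dir, "processed_data.csv"),
             molid = file.path(dir, "processed_molecular_identification.csv"))
  writeGeneralizedOutput(ds, files[["data"]], files[["molid"]],
                         massCol = massCol)
  if (merged) {
    pt <- peakTable(ds)
    pt[is.na(pt)] <- missingCode(ds)
    m <- data.frame(check.names = FALSE,
                    setNames(list(rownames(ds)), massCol),
                    as.data.frame(molTable(ds)), pt)
    files[["merged"]] <- file.path(dir, "merged.csv")
    write.csv(m, files[["merged"]], row.names = FALSE)
  }
  if (!is.null(comparisons)) {
    if (!is.list(comparisons) || inherits(comparisons, "DataFrame"))
      comparisons <- list(comparison = comparisons)
    for (nm in names(comparisons)) {
      cmp <- comparisons[[nm]]
      f <- file.path(dir, paste0("uniqueness_", nm, ".csv"))
      out <- data.frame(check.names = FALSE,
                        setNames(list(rownames(cmp)), massCol),
                        as.data.frame(cmp))
      write.csv(out, f, row.names = FALSE)
      files[[paste0("uniqueness_", nm)]] <- f
    }
    gs <- file.path(dir, "group_summary.csv")
    write.csv(summarizeDataset(ds), gs, row.names = FALSE)
    files[["group_summary"]] <- gs
  }
  if (!is.null(plots)) {
    for (nm in names(plots)) {
      f <- file.path(dir, paste0("plot_", nm, ".csv"))
      write.csv(plots[[nm]], f, row.names = FALSE)
      files[[paste0("plot_", nm)]] <- f
    }
  }
  if (report) {
    files[["report"]] <- file.path(dir, "report.html")
    generateReport(ds, comparisons = comparisons,
                   file = files[["report"]])
  }
  invisible(files)
}
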