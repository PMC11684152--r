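# Formula-to-database mapping against local lookup tables.  Live KEGG /
# MetaCyc queries are deliberately not performed: users supply (or cache) a
# mapping CSV, which keeps runs reproducible and license-clean.

#' Read and validate a formula mapping table
#'
#' @param file CSV with columns `formula`, `database` (`KEGG` or
#'   `MetaCyc`), `entry_type` (`compound`, `reaction`, `module`,
#'   `pathway`), `entry_id`, `entry_name`.
#' @return validated data.frame.
#' @export
readMappingTable <- function(file) {
  mt <- read.csv(file, check.names = FALSE, colClasses = "character")
  need <- c("formula", "database", "entry_type", "entry_id", "entry_name")
  miss <- setdiff(need, colnames(mt))
  if (length(miss))
    stop("mapping table is missing column(s): ",
         paste(miss, collapse = ", "))
  badDb <- setdiff(unique(mt$database), c("KEGG", "MetaCyc"))
  if (length(badDb))
    stop("unknown database(s): ", paste(badDb, collapse = ", "))
  badTy <- setdiff(unique(mt$entry_type),
                   c("compound", "reaction", "module", "pathway"))
  if (length(badTy))
    stop("unknown entry type(s): ", paste(badTy, collapse = ", "))
  key <- mt[c("formula", "database", "entry_type", "entry_id")]
  if (anyDuplicated(key))
    stop("duplicate (formula, database, entry_type, entry_id) rows")
  mt
}

#' Map peak formulas to database entries
#'
#' For each peak with a formula, returns up to `maxRecords` entries per
#' (database, entry type), ordered by entry id for determinism.  In long
#' layout every entry is its own row; in wide layout entries are
#' semicolon-joined into one cell per (database, entry type), with ids and
#' names in parallel columns, one row per formula-carrying peak.
#'
#' @param ds an [FTMSExperiment-class] whose molecular table has a
#'   `Formula` column (or element counts, from which Hill-order formulas
#'   are written).
#' @param table mapping table from [readMappingTable()].
#' @param maxRecords maximum entries per formula and (database, entry
#'   type); default 5.
#' @param layout `"long"` (default) or `"wide"`.
#' @return data.frame; long: columns `massId`, `formula`, `database`,
#'   `entry_type`, `entry_id`, `entry_name`; wide: `massId`, `formula` and
#'   `<database>_<entry_type>_ids` / `_names` columns (empty string = no
#'   match).
#' @export
mapFormulas <- function(ds, table, maxRecords = 5,
                        layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (maxRecords < 1) stop("maxRecords must be at least 1")
  rd <- molTable(ds)
  formula <- if ("Formula" %in% colnames(rd)) as.character(rd$Formula)
  else formulaString(rd$C, rd$H, rd$N, rd$O, rd$S, rd$P)
  has <- !is.na(formula) & nzchar(formula)
  ids <- rownames(ds)[has]
  formula <- formula[has]
  if (nrow(table) == 0L) {
    warning("mapping table is empty; no formulas mapped")
    table <- table[0, , drop = FALSE]
  }
  table <- table[order(table$formula, table$database, table$entry_type,
                       table$entry_id), , drop = FALSE]
  hit <- table[table$formula %in% formula, , drop = FALSE]
  # truncate to maxRecords within (formula, database, entry_type)
  grp <- paste(hit$formula, hit$database, hit$entry_type, sep = "\r")
  keep <- stats::ave(seq_len(nrow(hit)), grp,
                     FUN = seq_along) <= maxRecords
  hit <- hit[keep, , drop = FALSE]
  # a formula may back several peaks; expand to every peak carrying it
  expand <- lapply(seq_along(ids), function(i) {
    rows <- hit[hit$formula == formula[i], , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    data.frame(massId = ids[i], rows, row.names = NULL)
  })
  long <- do.call(rbind, c(expand,
                           list(data.frame(massId = character(0),
                                           formula = character(0),
                                           database = character(0),
                                           entry_type = character(0),
                                           entry_id = character(0),
                                           entry_name = character(0)))))
  if (layout == "long") return(long)
  combos <- unique(table[c("database", "entry_type")])
  wide <- data.frame(massId = ids, formula = formula)
  if (nrow(combos) == 0L)
    combos <- data.frame(database = character(0), entry_type = character(0))
  for (i in seq_len(nrow(combos))) {
    db <- combos$database[i]; ty <- combos$entry_type[i]
    sub <- long[long$database == db & long$entry_type == ty, , drop = FALSE]
    idCol <- vapply(ids, function(m)
      paste(sub$entry_id[sub$massId == m], collapse = ";"), "")
    nmCol <- vapply(ids, function(m)
      paste(sub$entry_name[sub$massId == m], collapse = ";"), "")
    wide[[paste(db, ty, "ids", sep = "_")]] <- unname(idCol)
    wide[[paste(db, ty, "names", sep = "_")]] <- unname(nmCol)
  }
  wide
}
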