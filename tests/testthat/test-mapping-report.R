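test_that("mapping respects the per-(database, entry type) maximum", {
  tab <- readMappingTable(writeMappingFixture())
  ds <- encodeMissing(makeToyDataset())
  long <- mapFormulas(ds, tab, maxRecords = 5, layout = "long")
  # 7 matching KEGG compounds truncated to 5
  expect_equal(sum(long$formula == "C6H12O6" &
                     long$entry_type == "compound"), 5)
  # deterministic id-order truncation keeps the smallest ids
  expect_setequal(long$entry_id[long$formula == "C6H12O6" &
                                  long$entry_type == "compound"],
                  sprintf("C%05d", 1:5))
  # long row count = sum over peaks of min(matches, max) per (db, type)
  perType <- table(tab$formula, paste(tab$database, tab$entry_type))
  expected <- 0
  for (f in c("C6H12O6", "C10H14N2"))
    expected <- expected + sum(pmin(perType[f, ], 5))
  expect_equal(nrow(long), expected)
  # formulas absent from the table produce no long rows
  expect_false("C18H36O2" %in% long$formula)
})

test_that("wide and long layouts carry identical information", {
  tab <- readMappingTable(writeMappingFixture())
  ds <- encodeMissing(makeToyDataset())
  long <- mapFormulas(ds, tab, maxRecords = 3, layout = "long")
  wide <- mapFormulas(ds, tab, maxRecords = 3, layout = "wide")
  # every formula-bearing peak gets a wide row; unmatched cells are empty
  expect_equal(nrow(wide), sum(!is.na(molTable(ds)$Formula)))
  expect_equal(wide$KEGG_compound_ids[wide$formula == "C18H36O2"], "")
  # exploding wide cells on ";" reproduces the long table
  rebuilt <- NULL
  idCols <- grep("_ids$", colnames(wide), value = TRUE)
  for (col in idCols) {
    dbty <- sub("_ids$", "", col)
    db <- sub("_.*", "", dbty)
    ty <- sub("^[^_]*_", "", dbty)
    for (i in seq_len(nrow(wide))) {
      if (!nzchar(wide[[col]][i])) next
      ids <- strsplit(wide[[col]][i], ";")[[1]]
      rebuilt <- rbind(rebuilt,
                       data.frame(massId = wide$massId[i],
                                  formula = wide$formula[i], database = db,
                                  entry_type = ty, entry_id = ids))
    }
  }
  key <- function(d) sort(paste(d$massId, d$database, d$entry_type,
                                d$entry_id))
  expect_equal(key(rebuilt), key(long))
})

test_that("mapping table validation and the empty-table warning", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.csv")
  writeLines(c("formula,database,entry_type,entry_id,entry_name",
               "C6H12O6,NotADb,compound,X,foo"), f)
  expect_error(readMappingTable(f), "unknown database")
  writeLines(c("formula,database,entry_type,entry_id,entry_name",
               "C6H12O6,KEGG,compound,X,foo",
               "C6H12O6,KEGG,compound,X,foo"), f)
  expect_error(readMappingTable(f), "duplicate")
  writeLines("formula,database,entry_type,entry_id,entry_name", f)
  empty <- readMappingTable(f)
  ds <- encodeMissing(makeToyDataset())
  expect_warning(out <- mapFormulas(ds, empty), "empty")
  expect_equal(nrow(out), 0)
  expect_error(mapFormulas(ds, readMappingTable(writeMappingFixture()),
                           maxRecords = 0), "at least 1")
})

test_that("report covers provenance, equations and filters deterministically", {
  withr::local_options(ftmseda.timestamp = "2026-01-01 00:00:00 UTC")
  sim <- makeSimDataset(nPeaks = 80, samplesPerGroup = c(4, 4), seed = 19)
  ds <- calculateProperties(sim$dataset)
  ds <- applyFilters(ds, list(massFilter(200, 900), formulaFilter()),
                     groups = sim$groups)
  cmp <- gtestUniqueness(ds, sim$groups)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "r1.html"); f2 <- file.path(dir, "r2.html")
  html <- generateReport(ds, comparisons = list(gtest = cmp), file = f1)
  # every provenance step name appears in the report
  for (s in vapply(provenance(ds), `[[`, "", "step"))
    expect_match(html, s, fixed = TRUE)
  # calculated properties rendered with equations
  expect_match(html, "NOSC = 4 - (4C + H - 3N - 2O - 2S + 5P) / C",
               fixed = TRUE)
  expect_match(html, "60.3 - 28.5", fixed = TRUE)
  # one filter row per filter step
  expect_equal(lengths(regmatches(html, gregexpr("mass range", html))) +
                 lengths(regmatches(html, gregexpr("formula assigned",
                                                   html))) >= 2, TRUE)
  generateReport(ds, comparisons = list(gtest = cmp), file = f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
  expect_error(generateReport(FTMSExperiment(
    matrix(1, 1, 1, dimnames = list("m", "s")),
    data.frame(C = 6, H = 12)), file = f1), "provenance is empty")
})

test_that("export bundle round-trips losslessly and gates uniqueness CSVs", {
  sim <- makeSimDataset(nPeaks = 60, samplesPerGroup = c(4, 4), seed = 29)
  ds <- calculateProperties(sim$dataset)
  dir <- withr::local_tempdir()
  # no comparisons -> no uniqueness or group summary files
  files <- exportBundle(ds, file.path(dir, "plain"), report = FALSE)
  expect_false(any(grepl("uniqueness", names(files))))
  cmp <- gtestUniqueness(ds, sim$groups)
  vk <- vanKrevelenTable(ds)
  files <- exportBundle(ds, file.path(dir, "full"),
                        comparisons = list(gtest = cmp),
                        plots = list(vk = vk), merged = TRUE)
  expect_true(file.exists(files[["uniqueness_gtest"]]))
  expect_true(file.exists(files[["report"]]))
  merged <- read.csv(files[["merged"]], check.names = FALSE)
  expect_equal(nrow(merged), nrow(ds))
  # re-import reproduces observed values and formulas
  back <- readGeneralizedInput(files[["data"]], files[["molid"]])
  back <- encodeMissing(back)
  expect_equal(peakTable(back), peakTable(ds))
  expect_equal(molTable(back)$Formula, molTable(ds)$Formula)
  expect_equal(molTable(back)$C, molTable(ds)$C)
})
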