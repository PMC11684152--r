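# small hand-written CoreMS-style files
writeCoremsFixture <- function(dir = withr::local_tempdir(.local_envir =
                                                            parent.frame())) {
  f1 <- file.path(dir, "sampleA.csv")
  f2 <- file.path(dir, "sampleB.csv")
  writeLines(c(
    "Calibrated m/z,Peak Height,Molecular Formula,Confidence Score,m/z Error (ppm),Is Isotopologue",
    "180.06339,1000,C6H12O6,0.95,0.10,0",
    "180.06339,1000,C5H8N2O5,0.40,1.50,0",
    "162.11570,500,C10H14N2,0.80,0.30,0",
    "162.11570,500,C11H18,0.80,0.80,0",
    "284.27153,900,C18H36O2,0.60,0.20,0"), f1)
  writeLines(c(
    "Calibrated m/z,Peak Height,Molecular Formula,Confidence Score,m/z Error (ppm),Is Isotopologue",
    "180.06339,800,C6H12O6,0.90,0.15,0",
    "78.04695,300,C6H6,0.30,0.50,0",
    "79.05000,250,C6H7,0.30,0.50,1"), f2)
  c(f1, f2)
}

test_that("readCoreMS concatenates files and auto-detects columns", {
  files <- writeCoremsFixture()
  recs <- readCoreMS(files)
  expect_equal(nrow(recs), 8)
  expect_setequal(unique(recs$SampleID), c("sampleA", "sampleB"))
  expect_true(all(c("MZ", "Intensity", "Formula", "Confidence",
                    "MassError", "Isotope") %in% colnames(recs)))
})

test_that("missing required columns error; explicit map wins", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "s.csv")
  writeLines(c("mz_calibrated,height,Molecular Formula",
               "100,1,C6H12O6"), f)
  expect_error(readCoreMS(f), "Confidence")
  writeLines(c("weird_mz,height,Molecular Formula,myscore",
               "100,1,C6H12O6,0.5"), f)
  recs <- readCoreMS(f, columnMap = c(MZ = "weird_mz",
                                      Confidence = "myscore"))
  expect_equal(recs$MZ, 100)
  expect_equal(recs$Confidence, 0.5)
})

test_that("confidence scores outside the unit interval are rejected", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "s.csv")
  writeLines(c("m/z,Peak Height,Formula,Confidence Score",
               "100,1,C6H12O6,1.7"), f)
  expect_error(readCoreMS(f), "outside \\[0,1\\]")
})

test_that("confidence profile matches brute-force filtering at each threshold", {
  files <- writeCoremsFixture()
  recs <- readCoreMS(files)
  grid <- c(0, 0.3, 0.5, 0.8, 0.95, 1)
  prof <- confidenceProfile(recs, grid)
  for (i in seq_along(grid)) {
    keep <- recs$Confidence >= grid[i]
    expect_equal(prof$Retained[i], sum(keep))
    if (any(keep))
      expect_equal(prof$MeanAbsMassError[i], mean(abs(recs$MassError[keep])))
  }
  expect_equal(prof$Retained[1], nrow(recs))     # t = 0 keeps all
  expect_true(all(diff(prof$Retained) <= 0))     # monotone non-increasing
  expect_error(confidenceProfile(recs, numeric(0)), "empty")
  expect_error(confidenceProfile(recs, c(0, 1.2)), "within")
})

test_that("confidence filter drops low scores and errors when empty", {
  recs <- readCoreMS(writeCoremsFixture())
  out <- applyConfidenceFilter(recs, 0.5)
  expect_equal(nrow(out), sum(recs$Confidence >= 0.5))
  expect_equal(nrow(applyConfidenceFilter(recs, 0)), nrow(recs))
  expect_error(applyConfidenceFilter(recs, 0.99), "removes every record")
  expect_error(applyConfidenceFilter(recs, 1.5), "within")
})

test_that("formula resolution maximizes the criterion with stated tie-breaks", {
  recs <- readCoreMS(writeCoremsFixture())
  res <- resolveFormulas(recs, "max_confidence")
  df <- as.data.frame(res)
  expect_false(anyDuplicated(df[c("SampleID", "MZ")]) > 0)
  # plain max confidence
  expect_equal(df$Formula[df$SampleID == "sampleA" &
                            abs(df$MZ - 180.06339) < 1e-6], "C6H12O6")
  # tied confidence (0.80 vs 0.80): smaller |mass error| wins
  expect_equal(df$Formula[df$SampleID == "sampleA" &
                            abs(df$MZ - 162.11570) < 1e-6], "C10H14N2")
  # single candidate kept
  expect_true("C18H36O2" %in% df$Formula)
  # still-tied candidates fall back to lexicographically smallest formula
  dir <- withr::local_tempdir()
  f <- file.path(dir, "t.csv")
  writeLines(c("m/z,Peak Height,Formula,Confidence Score,m/z Error (ppm)",
               "100,1,C9H9,0.5,0.3", "100,1,C2H2,0.5,0.3"), f)
  tied <- resolveFormulas(readCoreMS(f))
  expect_equal(as.data.frame(tied)$Formula, "C2H2")
})

test_that("pivot merges on resolved formula and conserves observed cells", {
  recs <- resolveFormulas(readCoreMS(writeCoremsFixture()))
  ds <- pivotToDataset(recs)
  df <- as.data.frame(recs)
  # isotope-annotated formulas stay distinct peaks
  expect_equal(nrow(ds), length(unique(ifelse(
    df$Isotope != "0", paste(df$Formula, df$Isotope), df$Formula))))
  expect_equal(sum(!is.na(peakTable(ds))), nrow(df))
  # C6H12O6 observed in both samples on one row
  glu <- peakTable(ds)["C6H12O6", ]
  expect_equal(unname(glu[c("sampleA", "sampleB")]), c(1000, 800))
  # formula seen in one sample only -> one observed, one missing cell
  ste <- peakTable(ds)["C18H36O2", ]
  expect_equal(sum(is.na(ste)), 1)
  expect_true(isMissingEncoded(ds))
})

test_that("pivot refuses unresolved multi-candidate records", {
  recs <- readCoreMS(writeCoremsFixture())
  expect_error(pivotToDataset(recs), "resolveFormulas first")
})
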