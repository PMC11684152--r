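test_that("distance matrices match naive double-loop oracles", {
  sim <- makeSimDataset(nPeaks = 40, samplesPerGroup = c(2, 2), seed = 6)
  ds <- sim$dataset
  pt <- peakTable(ds)
  pt0 <- pt; pt0[is.na(pt0)] <- 0
  dEuc <- distanceMatrix(ds, "euclidean")
  dMan <- distanceMatrix(ds, "manhattan")
  dJac <- distanceMatrix(ds, "jaccard_presence")
  for (i in seq_len(ncol(pt))) for (j in seq_len(ncol(pt))) {
    expect_equal(dEuc[i, j], sqrt(sum((pt0[, i] - pt0[, j])^2)),
                 tolerance = 1e-12)
    expect_equal(dMan[i, j], sum(abs(pt0[, i] - pt0[, j])),
                 tolerance = 1e-12)
    pi <- !is.na(pt[, i]); pj <- !is.na(pt[, j])
    expected <- if (!any(pi | pj)) 0 else
      1 - sum(pi & pj) / sum(pi | pj)
    expect_equal(dJac[i, j], expected, tolerance = 1e-12)
  }
  expect_equal(diag(dEuc), setNames(rep(0, 4), colnames(pt)))
})

test_that("identical columns give zero distance; disjoint presence gives 1", {
  pt <- matrix(c(1, NA, 1, NA, NA, 2), 2, 3,
               dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  ds <- FTMSExperiment(pt[, c(1, 1, 3)], data.frame(C = c(6, 7),
                                                    H = c(12, 14)),
                       missingEncoded = TRUE)
  colnames(ds) <- c("s1", "s2", "s3")
  d <- distanceMatrix(ds, "bray_curtis")
  expect_equal(d["s1", "s2"], 0)
  dj <- distanceMatrix(ds, "jaccard_presence")
  expect_equal(dj["s1", "s3"], 1)  # disjoint presence sets
})

test_that("PCoA reconstructs euclidean configurations", {
  set.seed(21)
  xy <- matrix(rnorm(16), 8, 2,
               dimnames = list(paste0("s", 1:8), NULL))
  d <- as.matrix(dist(xy))
  pc <- runPCoA(d)
  rec <- as.matrix(dist(pc$coordinates))
  expect_lt(max(abs(rec - d)), 1e-8)
  expect_true(all(diff(pc$R2) <= 1e-12))     # non-increasing
  expect_lte(sum(pc$R2), 1 + 1e-12)
  expect_equal(rownames(pc$coordinates), rownames(d))
})

test_that("PCoA agrees with an independent classical-scaling implementation", {
  skip_if_not_installed("ape")
  sim <- makeSimDataset(nPeaks = 80, samplesPerGroup = c(4, 4), seed = 13)
  d <- distanceMatrix(sim$dataset, "bray_curtis")
  pc <- runPCoA(d)
  ref <- ape::pcoa(stats::as.dist(d))
  k <- ncol(pc$coordinates)
  for (ax in seq_len(min(k, 3))) {
    # axes defined up to sign
    expect_equal(abs(pc$coordinates[, ax]),
                 abs(ref$vectors[, ax]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("two points map to +/- d/2 with R2 = 1", {
  d <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  pc <- runPCoA(d)
  expect_equal(sort(pc$coordinates[, 1]), c(a = -1.5, b = 1.5),
               ignore_attr = TRUE)
  expect_equal(pc$R2, 1)
  # duplicated sample -> coincident coordinates
  d3 <- matrix(c(0, 0, 4, 0, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  pc3 <- runPCoA(d3)
  expect_equal(pc3$coordinates["a", ], pc3$coordinates["b", ],
               tolerance = 1e-8)
})

test_that("PCoA input validation", {
  expect_error(runPCoA(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(runPCoA(matrix(c(1, 0, 0, 1), 2, 2)), "zero diagonal")
})

test_that("van Krevelen and Kendrick tables exclude incomplete peaks", {
  ds <- calculateProperties(encodeMissing(makeToyDataset()))
  vk <- vanKrevelenTable(ds, colorBy = "NOSC")
  expect_equal(nrow(vk), sum(!is.na(molTable(ds)$C)))  # no-formula excluded
  glu <- vk[vk$Formula == "C6H12O6", ]
  expect_equal(c(glu$x, glu$y), c(1, 2))
  expect_true(all(is.finite(vk$x) & is.finite(vk$y)))
  expect_equal(attr(vk, "kind"), "van_krevelen")
  kt <- kendrickTable(ds, colorBy = "OtoC")
  expect_equal(nrow(kt), nrow(vk))
  expect_true(all(kt$y >= 0 & kt$y < 1))
  expect_error(vanKrevelenTable(makeToyDataset()), "calculateProperties")
  expect_error(vanKrevelenTable(ds, colorBy = "NoSuch"), "unknown color")
})

test_that("comparison labels attach to plot tables with conserved counts", {
  sim <- makeSimDataset(nPeaks = 150, samplesPerGroup = c(5, 5), seed = 17)
  ds <- calculateProperties(sim$dataset)
  cmp <- gtestUniqueness(ds, sim$groups)
  vk <- vanKrevelenTable(ds, comparison = cmp)
  cmpCounts <- table(as.character(cmp[vk$massId, "uniqueness"]))
  expect_equal(table(vk$uniqueness)[names(cmpCounts)], cmpCounts)
})

test_that("scatter tables keep peaks with both values and support x = y", {
  ds <- calculateProperties(encodeMissing(makeToyDataset()))
  st <- scatterTable(ds, "DBE", "AI")
  rd <- molTable(ds)
  expect_equal(nrow(st), sum(!is.na(rd$DBE) & !is.na(rd$AI)))
  stSame <- scatterTable(ds, "NOSC", "NOSC")
  expect_equal(stSame$x, stSame$y)
  expect_error(scatterTable(ds, "NOSC", "NoSuch"), "unknown column")
})

test_that("density curves normalize and respect group structure", {
  sim <- makeSimDataset(nPeaks = 300, samplesPerGroup = c(5, 5), seed = 23)
  ds <- calculateProperties(sim$dataset)
  dt <- densityTable(ds, "NOSC", by = "sample")
  for (u in unique(dt$unit)) {
    cur <- dt[dt$unit == u, ]
    integral <- sum(diff(cur$x) * (head(cur$density, -1) +
                                     tail(cur$density, -1)) / 2)
    expect_equal(integral, 1, tolerance = 1e-3)
  }
  # all curves share one grid
  expect_equal(length(unique(dt$x)), 512)
  dg <- densityTable(ds, "NOSC", by = "group", includeCombined = TRUE)
  expect_setequal(unique(dg$unit), c("G1", "G2", "combined"))
})

test_that("shifted group property distributions shift the density modes", {
  # two groups of peaks with clearly different NOSC-affecting composition:
  # build directly with distinct H:C regimes per group presence
  pt <- matrix(NA_real_, 60, 6,
               dimnames = list(sprintf("m%02d", 1:60),
                               c(paste0("a", 1:3), paste0("b", 1:3))))
  pt[1:30, 1:3] <- 10    # peaks 1-30 only in group A
  pt[31:60, 4:6] <- 10   # peaks 31-60 only in group B
  mt <- data.frame(C = 10, H = c(rep(c(18, 20, 22), 10),
                                 rep(c(6, 8, 10), 10)),
                   O = c(rep(1, 30), rep(6, 30)))
  ds <- FTMSExperiment(pt, mt, missingEncoded = TRUE)
  ds <- calculateProperties(ds, calc = "nosc")
  g <- setNames(rep(c("A", "B"), each = 3), colnames(pt))
  dt <- densityTable(ds, "NOSC", by = "group", groups = g)
  modeOf <- function(u) {
    cur <- dt[dt$unit == u, ]
    cur$x[which.max(cur$density)]
  }
  # group B carries more oxidized formulas -> larger NOSC mode
  expect_lt(modeOf("A"), modeOf("B"))
})

test_that("QC tables are consistent with the dataset summary", {
  sim <- makeSimDataset(nPeaks = 100, samplesPerGroup = c(3, 3), seed = 31)
  ds <- sim$dataset
  qc <- qcTables(ds, groups = sim$groups)
  sm <- summarizeDataset(ds)
  expect_equal(qc$counts$ObservedPeaks, sm$ObservedPeaks)
  expect_equal(qc$boxplot$Median, sm$Median)
  # group filter restricts columns
  qcG <- qcTables(ds, groups = sim$groups, groupFilter = "G1")
  expect_equal(nrow(qcG$counts), 3)
  expect_true(all(qcG$counts$Group == "G1"))
  # presence/absence scale degenerates the boxplot to {0,1}
  qcPA <- qcTables(ds, scale = "presence_absence")
  expect_true(all(qcPA$boxplot$Max <= 1))
})
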