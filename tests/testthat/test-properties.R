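test_that("elemental ratios follow the definitions and degenerate rules", {
  r <- elementRatios(C = 6, H = 12, O = 6)
  expect_equal(r$OtoC, 1)
  expect_equal(r$HtoC, 2)
  expect_equal(elementRatios(C = 10, H = 14, N = 2)$NtoC, 0.2)
  expect_true(is.na(elementRatios(C = 6, H = 12)$NtoP))  # P = 0
  expect_true(all(is.na(elementRatios(C = NA, H = NA))))
})

test_that("Kendrick mass and defect follow the CH2 rescaling", {
  k <- kendrickMassDefect(14.01565)
  expect_equal(k$KendrickMass, 14)
  expect_equal(k$KendrickDefect, 0)
  # independent hand arithmetic for stearic acid C18H36O2
  m <- 284.27153
  kmOracle <- m * 14 / 14.01565
  expect_equal(kendrickMassDefect(m)$KendrickMass, kmOracle,
               tolerance = 1e-12)
  expect_equal(kendrickMassDefect(m)$KendrickDefect,
               ceiling(kmOracle) - kmOracle, tolerance = 1e-12)
  # homologous-series symmetry
  k2 <- kendrickMassDefect(c(m, m + 14.01565))
  expect_equal(diff(k2$KendrickDefect), 0, tolerance = 1e-9)
  expect_true(all(k2$KendrickDefect >= 0 & k2$KendrickDefect < 1))
  # rounding convention stays available
  kr <- kendrickMassDefect(200.1, convention = "round")
  expect_equal(kr$KendrickDefect,
               round(200.1 * 14 / 14.01565) - 200.1 * 14 / 14.01565)
  expect_error(kendrickMassDefect(-1), "positive")
})

test_that("NOSC and GFE match hand-computed oxidation states", {
  expect_equal(noscGfe(C = 1, H = 4)$NOSC, -4)              # methane
  expect_equal(noscGfe(C = 1, H = 0, O = 2)$NOSC, 4)        # CO2
  g <- noscGfe(C = 6, H = 12, O = 6)                        # glucose
  expect_equal(g$NOSC, 0)
  expect_equal(g$GFE, 60.3)
  expect_true(is.na(noscGfe(C = NA, H = NA)$NOSC))
})

test_that("AI, AImod and DBE follow the clamped conventions", {
  b <- aiDbe(C = 6, H = 6)   # benzene
  expect_equal(b$DBE, 4)     # 1 + 0.5 * (12 - 6)
  expect_equal(b$AI, 2 / 3)  # (1 + 6 - 3) / 6
  expect_equal(aiDbe(C = 6, H = 12, O = 6)$AI, 0)  # denominator 0 -> clamp
  expect_true(is.na(aiDbe(C = 6, H = 12, O = 6, clamp = FALSE)$AI))
  # negative computed AImod clamps to 0 (or NA when clamping is off)
  expect_equal(aiDbe(C = 6, H = 12, O = 3)$AImod, 0)
  expect_true(is.na(aiDbe(C = 6, H = 12, O = 3, clamp = FALSE)$AImod))
  expect_equal(aiDbe(C = 10, H = 10, O = 2)$AImod,
               (1 + 10 - 1 - 5) / (10 - 1))
})

test_that("elemental composition concatenates symbols in C,H,N,O,S,P order", {
  expect_equal(elementalComposition(C = 6, H = 12, O = 6), "CHO")
  expect_equal(elementalComposition(C = 5, H = 9, N = 1, O = 4, S = 1),
               "CHNOS")
  expect_equal(elementalComposition(C = 2, H = 6), "CH")
  expect_true(is.na(elementalComposition(C = NA, H = NA)))
})

test_that("compound classes come from half-open van Krevelen rectangles", {
  expect_equal(assignCompoundClass(0.05, 2.0), "Lipid")
  expect_equal(assignCompoundClass(5, 5), "Other")
  # shared edge O:C = 0.3 belongs to Protein (min-inclusive), not Lipid
  expect_equal(assignCompoundClass(0.3, 2.0), "Protein")
  expect_true(is.na(assignCompoundClass(NA, 1)))
  # overlapping rectangles are all reported, joined in precedence order
  bs <- data.frame(class = c("A", "B"), ocmin = c(0, 0.1),
                   ocmax = c(0.5, 0.6), hcmin = c(1, 1),
                   hcmax = c(2, 2), precedence = c(1, 2))
  expect_equal(assignCompoundClass(0.2, 1.5, bs), "A;B")
})

test_that("boundary sets are validated", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "b.csv")
  writeLines(c("class,ocmin,ocmax,hcmin,hcmax,precedence",
               "Bad,0.5,0.5,1,2,1"), f)
  expect_error(readBoundarySet(f), "positive area")
  writeLines(c("class,ocmin,ocmax,hcmin,hcmax", "A,0,1,0,1"), f)
  expect_error(readBoundarySet(f), "missing column")
})

test_that("calculateProperties appends columns; no formula means no value", {
  ds <- calculateProperties(encodeMissing(makeToyDataset()))
  rd <- molTable(ds)
  expect_true(all(c("OtoC", "NOSC", "GFE", "AI", "DBE", "KendrickMass",
                    "ElComposition", "CompoundClass") %in% colnames(rd)))
  noF <- is.na(rd$C)
  expect_true(any(noF))
  for (col in c("OtoC", "HtoC", "NOSC", "GFE", "AI", "DBE",
                "ElComposition", "CompoundClass"))
    expect_true(all(is.na(rd[[col]][noF])), info = col)
  # GFE is an affine function of NOSC, exactly
  has <- !is.na(rd$NOSC)
  expect_equal(rd$GFE[has], 60.3 - 28.5 * rd$NOSC[has])
})

test_that("KMD is invariant across a CH2 homologous series", {
  masses <- 200.08 + (0:29) * 14.01565
  kmd <- kendrickMassDefect(masses)$KendrickDefect
  expect_lt(max(kmd) - min(kmd), 1e-9)
})

test_that("NOSC stays within [-4, 4] on generated valence-plausible formulas", {
  sim <- makeSimDataset(nPeaks = 400, seed = 9)
  rd <- molTable(calculateProperties(sim$dataset, calc = "nosc"))
  v <- rd$NOSC[!is.na(rd$NOSC)]
  expect_true(all(v >= -4 & v <= 4))
})

test_that("property summaries restrict to observed peaks and conserve counts", {
  ds <- calculateProperties(encodeMissing(makeToyDataset()))
  ps <- propertySummary(ds, "NOSC", bins = 5)
  expect_equal(sum(ps$histogram$Count), sum(!is.na(molTable(ds)$NOSC)))
  allRow <- ps$stats[ps$stats$Sample == "(all)", ]
  expect_equal(allRow$N, sum(!is.na(molTable(ds)$NOSC)))
  # constant property: min = median = max
  ds2 <- ds
  molTable(ds2)$Const <- 1.5
  ps2 <- propertySummary(ds2, "Const")
  expect_equal(ps2$stats$Min, ps2$stats$Max)
  expect_error(propertySummary(ds, "NoSuch"), "unknown property")
  ds3 <- ds
  molTable(ds3)$Empty <- NA_real_
  expect_error(propertySummary(ds3, "Empty"), "missing for every peak")
})
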