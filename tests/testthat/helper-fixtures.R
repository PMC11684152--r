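# Shared fixtures and independent oracles.  The oracles deliberately avoid
# the package's code paths: the formula oracle walks characters instead of
# tokenizing with a regex, the G-test oracle loops over cells, distances
# are double loops.

# character-walk molecular-formula parser (regex-free)
oracleParseFormula <- function(s) {
  s <- gsub(" ", "", s)
  counts <- c(C = 0, H = 0, N = 0, O = 0, S = 0, P = 0)
  i <- 1L
  n <- nchar(s)
  digits <- as.character(0:9)
  while (i <= n) {
    el <- substr(s, i, i)
    i <- i + 1L
    num <- ""
    while (i <= n && substr(s, i, i) %in% digits) {
      num <- paste0(num, substr(s, i, i))
      i <- i + 1L
    }
    counts[el] <- counts[el] + if (num == "") 1L else as.integer(num)
  }
  counts
}

# log-likelihood-ratio statistic for one 2x2 table, cell-by-cell loop
oracleG <- function(a, b, n1, n2) {
  O <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2, byrow = TRUE)
  rs <- rowSums(O); cs <- colSums(O); n <- sum(O)
  if (any(cs == 0)) return(list(G = 0, q = 1, p = 1))
  G <- 0
  for (r in 1:2) for (co in 1:2) {
    if (O[r, co] > 0) {
      E <- rs[r] * cs[co] / n
      G <- G + O[r, co] * log(O[r, co] / E)
    }
  }
  G <- 2 * G
  q <- 1 + ((n / rs[1] + n / rs[2] - 1) * (n / cs[1] + n / cs[2] - 1)) /
    (6 * n)
  list(G = G, q = q, p = pchisq(G / q, df = 1, lower.tail = FALSE))
}

# small in-memory dataset: 5 peaks x 4 samples, missing coded as 0
makeToyDataset <- function() {
  pt <- matrix(c(
    10, 12,  0,  9,
     0,  0,  5,  6,
     3,  0,  0,  0,
     7,  8,  9, 10,
     0,  4,  0,  0), nrow = 5, byrow = TRUE,
    dimnames = list(c("150.00000", "250.00000", "420.50000", "610.12345",
                      "905.00000"),
                    c("A_d01_r1", "A_d01_r2", "A_d04_r1", "A_d04_r2")))
  mt <- data.frame(
    Formula = c("C6H12O6", "C10H14N2", NA, "C18H36O2", "C6H6"),
    C = c(6, 10, NA, 18, 6), H = c(12, 14, NA, 36, 6),
    N = c(0, 2, NA, 0, 0), O = c(6, 0, NA, 2, 0),
    S = c(0, 0, NA, 0, 0), P = c(0, 0, NA, 0, 0),
    Isotope = c(0, 0, 1, 0, 0),
    Mass = c(150, 250, 420.5, 610.12345, 905))
  FTMSExperiment(pt, mt, dataScale = "abundance", missingCode = 0)
}

# write a toy generalized-format pair of CSVs; returns the two paths
writeToyInputFiles <- function(dir = withr::local_tempdir(.local_envir =
                                                            parent.frame())) {
  ds <- makeToyDataset()
  paths <- c(file.path(dir, "edata.csv"), file.path(dir, "emeta.csv"))
  writeGeneralizedOutput(ds, paths[1], paths[2], massCol = "MassID")
  paths
}

# random two-group dataset via the package generator, missing encoded
makeSimDataset <- function(nPeaks = 200, samplesPerGroup = c(5, 5),
                           seed = 11, ...) {
  sim <- simulateDataset(simulationConfig(nPeaks = nPeaks,
                                          samplesPerGroup = samplesPerGroup,
                                          seed = seed, ...))
  sim$dataset <- encodeMissing(sim$dataset)
  sim
}

# brute-force membership of a filter as an independent set oracle
bruteKeep <- function(ds, f, groupVec = NULL) {
  rd <- as.data.frame(molTable(ds))
  ids <- rownames(ds)
  if (f$kind == "mass") {
    return(ids[!is.na(rd$Mass) & rd$Mass >= f$min & rd$Mass <= f$max])
  }
  if (f$kind == "formula") return(ids[!is.na(rd$C)])
  if (f$kind == "minObserved") {
    obs <- !is.na(peakTable(ds))
    if (!isTRUE(f$perGroup)) return(ids[rowSums(obs) >= f$minCount])
    keep <- vapply(seq_along(ids), function(i) {
      any(vapply(unique(groupVec[!is.na(groupVec)]), function(g)
        sum(obs[i, names(groupVec)[!is.na(groupVec) & groupVec == g]]) >=
          f$minCount, TRUE))
    }, TRUE)
    return(ids[keep])
  }
  if (f$kind == "custom") {
    v <- rd[[f$column]]
    keep <- !is.na(v)
    if (!is.null(f$values)) keep <- keep & v %in% f$values
    if (!is.null(f$min)) keep <- keep & v >= f$min
    if (!is.null(f$max)) keep <- keep & v <= f$max
    return(ids[keep])
  }
  stop("unhandled kind")
}

# tiny fictional mapping fixture (synthetic ids, not real KEGG/MetaCyc
# entries)
writeMappingFixture <- function(dir = withr::local_tempdir(.local_envir =
                                                             parent.frame())) {
  f <- file.path(dir, "mapping.csv")
  rows <- c("formula,database,entry_type,entry_id,entry_name",
            paste0("C6H12O6,KEGG,compound,C", sprintf("%05d", 1:7),
                   ",sugar-", 1:7),
            "C6H12O6,KEGG,pathway,map00010,glycolysis-like",
            "C6H12O6,MetaCyc,reaction,RXN-001,hexose step",
            "C10H14N2,KEGG,compound,C99901,alkaloid-like",
            "C10H14N2,KEGG,reaction,R09001,demethylation")
  writeLines(rows, f)
  f
}
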