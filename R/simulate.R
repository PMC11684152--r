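# Synthetic FT-MS data with known ground truth.  The generator emulates the
# structure of formula-assigned peak data from a two-group study: per-peak
# molecular formulas drawn with van Krevelen-plausible H:C and O:C, peak
# presence governed by per-group Bernoulli probabilities, log-normal
# intensities, and (in CoreMS mode) multiple candidate formulas per peak
# with confidence scores.  It does not simulate spectra: no peak shapes,
# resolution or m/z noise.

#' Simulation configuration
#'
#' Defaults describe a realistic two-group soil-organic-matter-sized study
#' slice: 2000 peaks, 10 samples per group, 90% of peaks formula-assigned,
#' most peaks common to both groups (presence probability 0.7) and 20%
#' differential (0.9 vs 0.1).
#'
#' @param nPeaks number of peaks.
#' @param samplesPerGroup integer vector of group sizes.
#' @param groupLabels group labels.
#' @param pNull presence probability (both groups) for non-differential
#'   peaks.
#' @param pDiff length-2 presence probabilities (group 1, group 2) for
#'   differential peaks.
#' @param fracDifferential fraction of peaks whose presence probabilities
#'   differ between groups.
#' @param fracFormula fraction of peaks carrying a molecular formula.
#' @param cRange carbon-count range.
#' @param hcRange H:C window for rejection-sampling the hydrogen count.
#' @param ocRange O:C window for the oxygen count.
#' @param pN,pS,pP inclusion probabilities for N, S, P heteroatoms.
#' @param intensityMeanlog,intensitySdlog log-normal intensity parameters.
#' @param candidatesPerPeak candidate formulas per (sample, m/z) in CoreMS
#'   mode.
#' @param seed random seed; identical seeds give identical output.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(nPeaks = 2000,
                             samplesPerGroup = c(10, 10),
                             groupLabels = paste0("G", seq_along(samplesPerGroup)),
                             pNull = 0.7, pDiff = c(0.9, 0.1),
                             fracDifferential = 0.2,
                             fracFormula = 0.9,
                             cRange = c(4, 40), hcRange = c(0.2, 2.5),
                             ocRange = c(0, 1.2),
                             pN = 0.3, pS = 0.15, pP = 0.08,
                             intensityMeanlog = 18, intensitySdlog = 1.5,
                             candidatesPerPeak = 3, seed = 42) {
  cfg <- list(nPeaks = nPeaks, samplesPerGroup = samplesPerGroup,
              groupLabels = groupLabels, pNull = pNull, pDiff = pDiff,
              fracDifferential = fracDifferential,
              fracFormula = fracFormula, cRange = cRange,
              hcRange = hcRange, ocRange = ocRange, pN = pN, pS = pS,
              pP = pP, intensityMeanlog = intensityMeanlog,
              intensitySdlog = intensitySdlog,
              candidatesPerPeak = candidatesPerPeak, seed = seed)
  if (nPeaks < 1 || any(samplesPerGroup < 1))
    stop("degenerate configuration: need at least one peak and one sample")
  probs <- c(pNull, pDiff, fracDifferential, fracFormula, pN, pS, pP)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(cfg, class = "SimulationConfig")
}

# draw n unique molecular formulas (count matrix + strings) with
# valence-plausible H and van Krevelen-plausible ratios
.simFormulas <- function(n, cfg) {
  out <- NULL
  seen <- character(0)
  while (is.null(out) || nrow(out) < n) {
    m <- n * 2
    C <- sample(cfg$cRange[1]:cfg$cRange[2], m, replace = TRUE)
    H <- pmax(1, round(C * runif(m, cfg$hcRange[1], cfg$hcRange[2])))
    N <- ifelse(runif(m) < cfg$pN, sample(1:3, m, replace = TRUE), 0)
    H <- pmin(H, 2 * C + 2 + N)  # valence cap
    O <- round(C * runif(m, cfg$ocRange[1], cfg$ocRange[2]))
    S <- ifelse(runif(m) < cfg$pS, 1, 0)
    P <- ifelse(runif(m) < cfg$pP, 1, 0)
    f <- formulaString(C, H, N, O, S, P)
    keep <- !duplicated(f) & !(f %in% seen)
    add <- data.frame(C, H, N, O, S, P, Formula = f)[keep, , drop = FALSE]
    out <- rbind(out, add)
    seen <- c(seen, add$Formula)
  }
  out <- out[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a two-group FT-MS dataset with known truth
#'
#' Generates an [FTMSExperiment] in the generalized-format convention
#' (missing cells hold the missing code 0, not yet encoded) together with a
#' per-peak truth table flagging which peaks have genuinely different
#' presence probabilities between the groups.
#'
#' @param cfg a [simulationConfig()].
#' @return list with elements `dataset` (an [FTMSExperiment-class], groups
#'   assigned in `colData`), `truth` (data.frame `massId`, `differential`,
#'   and the per-group presence probabilities), and `groups` (named
#'   sample -> label vector).
#' @export
simulateDataset <- function(cfg = simulationConfig()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  ng <- length(cfg$samplesPerGroup)
  if (ng != 2L && cfg$fracDifferential > 0)
    stop("differential peaks are defined for exactly two groups")
  nPeaks <- cfg$nPeaks
  forms <- .simFormulas(nPeaks, cfg)
  mass <- monoisotopicMass(forms$C, forms$H, forms$N, forms$O, forms$S,
                           forms$P)
  # peaks without a formula keep their mass identifier but lose the counts
  noFormula <- seq_len(nPeaks) %in%
    sample.int(nPeaks, round((1 - cfg$fracFormula) * nPeaks))
  massId <- sprintf("%.5f", mass)
  # extremely close masses could collide after rounding; disambiguate
  while (anyDuplicated(massId)) {
    d <- duplicated(massId)
    mass[d] <- mass[d] + 0.00001
    massId <- sprintf("%.5f", mass)
  }
  diffPeak <- seq_len(nPeaks) %in%
    sample.int(nPeaks, round(cfg$fracDifferential * nPeaks))
  sampleNames <- unlist(lapply(seq_len(ng), function(g)
    sprintf("%s_r%02d", cfg$groupLabels[g],
            seq_len(cfg$samplesPerGroup[g]))))
  groupVec <- setNames(rep(cfg$groupLabels, cfg$samplesPerGroup),
                       sampleNames)
  pPres <- matrix(cfg$pNull, nrow = nPeaks, ncol = ng)
  if (any(diffPeak) && ng == 2L) {
    pPres[diffPeak, 1] <- cfg$pDiff[1]
    pPres[diffPeak, 2] <- cfg$pDiff[2]
  }
  pt <- matrix(0, nrow = nPeaks, ncol = length(sampleNames),
               dimnames = list(massId, sampleNames))
  for (j in seq_along(sampleNames)) {
    g <- match(groupVec[j], cfg$groupLabels)
    present <- runif(nPeaks) < pPres[, g]
    pt[present, j] <- rlnorm(sum(present), cfg$intensityMeanlog,
                             cfg$intensitySdlog)
  }
  mt <- forms
  mt$Mass <- mass
  mt[noFormula, c("C", "H", "N", "O", "S", "P")] <- NA_real_
  mt$Formula[noFormula] <- NA_character_
  ds <- FTMSExperiment(pt, mt, dataScale = "abundance", missingCode = 0)
  groups(ds) <- groupVec
  ds <- .addStep(ds, "simulate",
                 params = list(nPeaks = nPeaks,
                               samples = length(sampleNames),
                               seed = cfg$seed))
  truth <- data.frame(massId = massId, differential = diffPeak,
                      pGroup1 = pPres[, 1],
                      pGroup2 = if (ng >= 2) pPres[, 2] else NA_real_)
  list(dataset = ds, truth = truth, groups = groupVec)
}

#' Simulate CoreMS-style per-sample candidate files
#'
#' Writes one long-format CSV per sample with `candidatesPerPeak` candidate
#' formulas per observed m/z.  The true formula always carries the highest
#' confidence score and the smallest mass error, and is recorded in a truth
#' sidecar, so `resolveFormulas(method = "max_confidence")` recovers it
#' exactly.
#'
#' @param cfg a [simulationConfig()].
#' @param dir output directory for the CSV files.
#' @return list with `files` (paths, one per sample), `truth` (data.frame
#'   `SampleID`, `MZ`, `Formula` of the best candidate; also written to
#'   `truth_assignments.csv` in `dir`), and `dataset` (the underlying
#'   simulated [FTMSExperiment-class]).
#' @export
simulateCoreMSFiles <- function(cfg = simulationConfig(), dir = tempdir()) {
  sim <- simulateDataset(cfg)
  ds <- sim$dataset
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rd <- molTable(ds)
  has <- !is.na(rd$C)
  nCand <- max(1L, cfg$candidatesPerPeak)
  files <- character(0)
  truth <- NULL
  for (s in colnames(ds)) {
    v <- peakTable(ds)[, s]
    obs <- which(v != 0 & has)
    if (!length(obs)) next
    rows <- lapply(obs, function(i) {
      mz <- rd$Mass[i]
      true <- data.frame(
        mz = mz, height = unname(v[i]), formula = rd$Formula[i],
        conf = runif(1, 0.75, 0.98), err = rnorm(1, 0, 0.2))
      if (nCand > 1L) {
        # decoys: the same nominal mass bin, perturbed composition
        dC <- pmax(1, rd$C[i] + sample(c(-1, 1), nCand - 1, TRUE))
        dH <- pmax(1, rd$H[i] + sample(c(-2, 2, 4), nCand - 1, TRUE))
        decoy <- data.frame(
          mz = mz, height = unname(v[i]),
          formula = formulaString(dC, dH, rd$N[i], rd$O[i], rd$S[i],
                                  rd$P[i]),
          conf = runif(nCand - 1, 0.05, 0.70),
          err = rnorm(nCand - 1, 0, 2))
        rbind(true, decoy)
      } else true
    })
    df <- do.call(rbind, rows)
    out <- data.frame(check.names = FALSE,
                      "Calibrated m/z" = df$mz,
                      "Peak Height" = df$height,
                      "Molecular Formula" = df$formula,
                      "Confidence Score" = round(df$conf, 4),
                      "m/z Error (ppm)" = round(df$err, 4),
                      "Is Isotopologue" = 0)
    f <- file.path(dir, paste0(s, ".csv"))
    write.csv(out, f, row.names = FALSE)
    files <- c(files, f)
    truth <- rbind(truth, data.frame(SampleID = s, MZ = rd$Mass[obs],
                                     Formula = rd$Formula[obs]))
  }
  truthFile <- file.path(dir, "truth_assignments.csv")
  write.csv(truth, truthFile, row.names = FALSE)
  list(files = files, truth = truth, dataset = ds)
}
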