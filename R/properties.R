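# Per-peak chemical properties computed from element counts and mass.
# Every function is vectorized over peaks and propagates NA for peaks
# without a formula ("whenever applicable" semantics): missing inputs give
# missing properties, never an error.

#' Elemental ratios
#'
#' O:C, H:C, N:C, P:C and N:P ratios from element counts.  N:P is `NA` when
#' `P == 0`; all ratios are `NA` when `C` is missing or zero.
#'
#' @param C,H,N,O,S,P numeric vectors of element counts (recycled).
#' @return data.frame with columns `OtoC`, `HtoC`, `NtoC`, `PtoC`, `NtoP`.
#' @examples
#' elementRatios(C = 6, H = 12, O = 6)  # glucose: O:C = 1, H:C = 2
#' @export
elementRatios <- function(C, H, N = 0, O = 0, S = 0, P = 0) {
  n <- max(length(C), length(H), length(N), length(O), length(S), length(P))
  C <- rep_len(C, n); H <- rep_len(H, n); N <- rep_len(N, n)
  O <- rep_len(O, n); P <- rep_len(P, n)
  ok <- !is.na(C) & C >= 1
  div <- function(a, b, cond = rep(TRUE, n)) ifelse(cond, a / b, NA_real_)
  data.frame(
    OtoC = div(O, C, ok), HtoC = div(H, C, ok), NtoC = div(N, C, ok),
    PtoC = div(P, C, ok),
    NtoP = div(N, P, ok & !is.na(P) & P >= 1))
}

#' Kendrick mass and Kendrick mass defect
#'
#' Rescales the observed mass so the CH2 repeat unit weighs exactly 14:
#' `KM = mass * 14 / 14.01565`.  The defect is `ceiling(KM) - KM` (in
#' \[0, 1)) by default; the rounding convention `round(KM) - KM` is
#' available behind `convention = "round"`.  Members of a CH2 homologous
#' series share their Kendrick defect.
#'
#' @param mass numeric vector of masses (Da); must be positive.
#' @param convention `"ceiling"` (default) or `"round"`.
#' @return data.frame with columns `KendrickMass`, `KendrickDefect`.
#' @examples
#' kendrickMassDefect(14.01565)  # KM = 14, KMD = 0
#' @export
kendrickMassDefect <- function(mass, convention = c("ceiling", "round")) {
  convention <- match.arg(convention)
  if (any(!is.na(mass) & mass <= 0))
    stop("masses must be positive")
  km <- mass * 14 / .CH2_MASS
  # guard against floating-point noise pushing an exact-integer KM over the
  # next integer (e.g. the CH2 base mass itself)
  kmd <- switch(convention,
                ceiling = pmax(0, ceiling(km - 1e-9) - km),
                round = round(km) - km)
  data.frame(KendrickMass = km, KendrickDefect = kmd)
}

#' Nominal oxidation state of carbon and Gibbs free energy of carbon
#' oxidation
#'
#' `NOSC = 4 - (4C + H - 3N - 2O + 5P - 2S) / C` gives the average formal
#' oxidation state of carbon in the formula (−4 for methane, +4 for CO2, 0
#' for carbohydrates).  The standard-state Gibbs free energy of the carbon
#' oxidation half reaction follows the linear relation
#' `GFE = 60.3 - 28.5 * NOSC` (kJ per mol C): more reduced carbon stores
#' more oxidative energy.
#'
#' @inheritParams elementRatios
#' @return data.frame with columns `NOSC`, `GFE`.
#' @examples
#' noscGfe(C = 6, H = 12, O = 6)  # NOSC = 0, GFE = 60.3
#' @export
noscGfe <- function(C, H, N = 0, O = 0, S = 0, P = 0) {
  n <- max(length(C), length(H), length(N), length(O), length(S), length(P))
  C <- rep_len(C, n); H <- rep_len(H, n); N <- rep_len(N, n)
  O <- rep_len(O, n); S <- rep_len(S, n); P <- rep_len(P, n)
  ok <- !is.na(C) & C >= 1
  Z <- ifelse(is.na(N), 0, N); Oo <- ifelse(is.na(O), 0, O)
  Ss <- ifelse(is.na(S), 0, S); Pp <- ifelse(is.na(P), 0, P)
  nosc <- ifelse(ok, 4 - (4 * C + H - 3 * Z - 2 * Oo - 2 * Ss + 5 * Pp) / C,
                 NA_real_)
  data.frame(NOSC = nosc, GFE = 60.3 - 28.5 * nosc)
}

#' Aromaticity index and double-bond equivalents
#'
#' `DBE = 1 + (2C - H + N + P) / 2` counts rings plus double bonds.  The
#' aromaticity index `AI = (1 + C - O - S - 0.5 H) / (C - O - S - N - P)` is
#' clamped to 0 when its denominator is non-positive or the computed value
#' is negative (the standard convention for a lower bound on aromatic
#' character); `AImod` uses `0.5 O` in place of `O` in the numerator and
#' denominator, reflecting that at most half of the oxygen is likely to be
#' double-bonded.  Set `clamp = FALSE` to obtain `NA` instead of 0 in the
#' degenerate cases.
#'
#' @inheritParams elementRatios
#' @param clamp clamp degenerate AI values to 0 (default) or return `NA`.
#' @return data.frame with columns `AI`, `AImod`, `DBE`.
#' @examples
#' aiDbe(C = 6, H = 6)  # benzene: DBE = 4, AI = 2/3
#' @export
aiDbe <- function(C, H, N = 0, O = 0, S = 0, P = 0, clamp = TRUE) {
  n <- max(length(C), length(H), length(N), length(O), length(S), length(P))
  C <- rep_len(C, n); H <- rep_len(H, n); N <- rep_len(N, n)
  O <- rep_len(O, n); S <- rep_len(S, n); P <- rep_len(P, n)
  ok <- !is.na(C) & C >= 1
  N0 <- ifelse(is.na(N), 0, N); O0 <- ifelse(is.na(O), 0, O)
  S0 <- ifelse(is.na(S), 0, S); P0 <- ifelse(is.na(P), 0, P)
  dbe <- ifelse(ok, 1 + 0.5 * (2 * C - H + N0 + P0), NA_real_)
  aiOne <- function(Oeff) {
    num <- 1 + C - Oeff - S0 - 0.5 * H
    den <- C - Oeff - S0 - N0 - P0
    ai <- ifelse(ok & den > 0, num / den, NA_real_)
    if (clamp) {
      ai[ok & (is.na(ai) | ai < 0)] <- 0
      ai[!ok] <- NA_real_
    } else {
      ai[!is.na(ai) & ai < 0] <- NA_real_
    }
    ai
  }
  data.frame(AI = aiOne(O0), AImod = aiOne(0.5 * O0), DBE = dbe)
}

#' Elemental composition class
#'
#' Concatenates the symbols with non-zero count in the fixed order
#' C, H, N, O, S, P (e.g. `"CHO"`, `"CHNOS"`).
#'
#' @inheritParams elementRatios
#' @return character vector of labels; `NA` where `C` or `H` is missing.
#' @examples
#' elementalComposition(C = 6, H = 12, O = 6)  # "CHO"
#' @export
elementalComposition <- function(C, H, N = 0, O = 0, S = 0, P = 0) {
  cnt <- cbind(C = C, H = H, N = N, O = O, S = S, P = P)
  apply(cnt, 1L, function(v) {
    if (is.na(v[["C"]]) || is.na(v[["H"]])) return(NA_character_)
    v[is.na(v)] <- 0
    paste(names(v)[v > 0], collapse = "")
  })
}

# ---- compound-class boundaries ---------------------------------------------

#' Van Krevelen compound-class boundary sets
#'
#' A boundary set is a table of named axis-aligned rectangles in
#' (O:C, H:C) space with a precedence order; [assignCompoundClass()] labels
#' each peak with every class whose rectangle contains its point.  The
#' default set shipped with the package (`inst/extdata/
#' compound_class_boundaries.csv`) follows the van Krevelen regions commonly
#' used for natural organic matter; intervals are min-inclusive,
#' max-exclusive.
#'
#' @param file CSV with columns `class`, `ocmin`, `ocmax`, `hcmin`, `hcmax`,
#'   `precedence`.
#' @return data.frame of validated boundaries ordered by precedence.
#' @export
readBoundarySet <- function(file) {
  bs <- read.csv(file, check.names = FALSE)
  need <- c("class", "ocmin", "ocmax", "hcmin", "hcmax", "precedence")
  miss <- setdiff(need, colnames(bs))
  if (length(miss))
    stop("boundary set is missing column(s): ", paste(miss, collapse = ", "))
  if (any(bs$ocmin >= bs$ocmax) || any(bs$hcmin >= bs$hcmax))
    stop("boundary rectangles must have positive area (min < max)")
  if (anyDuplicated(bs$precedence) || anyDuplicated(bs$class))
    stop("classes and precedence values must be unique")
  bs[order(bs$precedence), , drop = FALSE]
}

#' @rdname readBoundarySet
#' @export
defaultBoundarySet <- function() {
  readBoundarySet(system.file("extdata", "compound_class_boundaries.csv",
                              package = "ftmseda", mustWork = TRUE))
}

#' Assign van Krevelen compound classes
#'
#' Labels each (O:C, H:C) point with every boundary-set class whose
#' rectangle contains it (min-inclusive, max-exclusive), joined by `";"` in
#' precedence order; points inside no rectangle get `"Other"`.
#'
#' @param OtoC,HtoC numeric vectors of elemental ratios.
#' @param boundarySet a boundary table from [readBoundarySet()] /
#'   [defaultBoundarySet()].
#' @return character vector of class labels (`NA` where a ratio is missing).
#' @examples
#' assignCompoundClass(0.05, 2.0)  # "Lipid"
#' @export
assignCompoundClass <- function(OtoC, HtoC,
                                boundarySet = defaultBoundarySet()) {
  vapply(seq_along(OtoC), function(i) {
    oc <- OtoC[i]; hc <- HtoC[i]
    if (is.na(oc) || is.na(hc)) return(NA_character_)
    inside <- oc >= boundarySet$ocmin & oc < boundarySet$ocmax &
      hc >= boundarySet$hcmin & hc < boundarySet$hcmax
    if (!any(inside)) "Other"
    else paste(boundarySet$class[inside], collapse = ";")
  }, "")
}

# ---- dataset-level wrapper --------------------------------------------------

#' Compute chemical properties and append them to the molecular table
#'
#' Appends the selected calculated-property columns to `molTable(ds)`:
#' elemental ratios (`OtoC`, `HtoC`, `NtoC`, `PtoC`, `NtoP`), Kendrick mass
#' and defect, `NOSC` and `GFE`, `AI`/`AImod`/`DBE`, the elemental
#' composition label `ElComposition`, and the van Krevelen `CompoundClass`.
#' Peaks without a formula get `NA` in every property column.
#'
#' @param ds an [FTMSExperiment-class].
#' @param calc character vector of property groups to compute; any of
#'   `"ratios"`, `"kendrick"`, `"nosc"`, `"ai"`, `"elcomp"`, `"class"`
#'   (default: all).
#' @param boundarySet boundary table for `"class"`.
#' @param kendrickConvention passed to [kendrickMassDefect()].
#' @return the dataset with property columns appended and a provenance step
#'   recorded.
#' @export
calculateProperties <- function(ds,
                                calc = c("ratios", "kendrick", "nosc",
                                         "ai", "elcomp", "class"),
                                boundarySet = defaultBoundarySet(),
                                kendrickConvention = "ceiling") {
  calc <- match.arg(calc, several.ok = TRUE)
  rd <- molTable(ds)
  C <- rd$C; H <- rd$H; N <- rd$N; O <- rd$O; S <- rd$S; P <- rd$P
  add <- function(df) for (nm in colnames(df)) rd[[nm]] <<- df[[nm]]
  if (any(c("ratios", "class") %in% calc)) {
    ratios <- elementRatios(C, H, N, O, S, P)
    if ("ratios" %in% calc) add(ratios)
  }
  if ("kendrick" %in% calc) {
    mass <- rd$Mass
    if (is.null(mass))
      mass <- suppressWarnings(as.numeric(rownames(ds)))
    if (all(is.na(mass)))
      stop("Kendrick properties need a numeric 'Mass' column or numeric ",
           "mass identifiers")
    kd <- kendrickMassDefect(mass, convention = kendrickConvention)
    # properties stay missing for peaks without an assigned formula
    kd[is.na(C), ] <- NA_real_
    add(kd)
  }
  if ("nosc" %in% calc) add(noscGfe(C, H, N, O, S, P))
  if ("ai" %in% calc) add(aiDbe(C, H, N, O, S, P))
  if ("elcomp" %in% calc)
    rd$ElComposition <- elementalComposition(C, H, N, O, S, P)
  if ("class" %in% calc)
    rd$CompoundClass <- assignCompoundClass(ratios$OtoC, ratios$HtoC,
                                            boundarySet)
  rowData(ds) <- rd
  .addStep(ds, "calculate_properties", params = list(calc = calc))
}

#' Distribution summary of a calculated property
#'
#' Per-sample (over peaks observed in that sample) and overall min, median
#' and max of a molecular-table column, plus histogram bin counts over the
#' peaks that carry a value.
#'
#' @param ds an [FTMSExperiment-class] with missing encoded.
#' @param property name of a numeric column of `molTable(ds)`.
#' @param bins number of histogram bins.
#' @return list with elements `stats` (data.frame `Sample`, `N`, `Min`,
#'   `Median`, `Max`; `Sample == "(all)"` is the overall row) and
#'   `histogram` (data.frame `BinStart`, `BinEnd`, `Count` over all peaks
#'   with a value).
#' @export
propertySummary <- function(ds, property, bins = 30) {
  rd <- molTable(ds)
  if (!property %in% colnames(rd))
    stop("unknown property column: ", property)
  v <- rd[[property]]
  if (!is.numeric(v)) stop("property must be numeric: ", property)
  if (all(is.na(v)))
    stop("property '", property, "' is missing for every peak")
  if (!isMissingEncoded(ds))
    stop("encode missing values first (encodeMissing)")
  obs <- !is.na(peakTable(ds))
  one <- function(label, vals) {
    vals <- vals[!is.na(vals)]
    if (!length(vals))
      return(data.frame(Sample = label, N = 0L, Min = NA_real_,
                        Median = NA_real_, Max = NA_real_))
    data.frame(Sample = label, N = length(vals), Min = min(vals),
               Median = median(vals), Max = max(vals))
  }
  stats <- do.call(rbind, c(
    lapply(colnames(ds), function(s) one(s, v[obs[, s]])),
    list(one("(all)", v))))
  vv <- v[!is.na(v)]
  br <- seq(min(vv), max(vv), length.out = bins + 1L)
  if (min(vv) == max(vv)) br <- c(min(vv) - 0.5, max(vv) + 0.5)
  cnt <- tabulate(cut(vv, breaks = br, include.lowest = TRUE),
                  nbins = length(br) - 1L)
  list(stats = stats,
       histogram = data.frame(BinStart = br[-length(br)], BinEnd = br[-1L],
                              Count = cnt))
}
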