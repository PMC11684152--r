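#' Parse molecular formula strings into element counts
#'
#' Tokenizes Hill-notation formulas (`"C6H12O6"`, `"C10 H14 N2"`; spaces are
#' ignored) into counts of the six supported elements C, H, N, O, S, P.  A
#' missing count after an element symbol means 1.
#'
#' @param x character vector of formula strings; `NA` or `""` yields a row of
#'   `NA` counts.
#' @param strict if `TRUE` (default) an element outside \{C,H,N,O,S,P\} is an
#'   error; if `FALSE` such elements are ignored with a warning.
#' @return data.frame with integer columns `C`, `H`, `N`, `O`, `S`, `P`, one
#'   row per input formula.
#' @examples
#' parseMolecularFormula(c("C6H12O6", "C10H14N2", "CH4"))
#' @export
parseMolecularFormula <- function(x, strict = TRUE) {
  x <- as.character(x)
  out <- matrix(NA_integer_, nrow = length(x), ncol = length(.ELEMENTS),
                dimnames = list(NULL, .ELEMENTS))
  compact <- gsub("[[:space:]]", "", x)
  todo <- which(!is.na(compact) & nzchar(compact))
  if (length(todo)) {
    toks <- regmatches(compact[todo],
                       gregexpr("[A-Z][a-z]?[0-9]*", compact[todo]))
    for (i in seq_along(todo)) {
      s <- compact[todo[i]]
      tk <- toks[[i]]
      if (paste(tk, collapse = "") != s)
        stop("cannot parse molecular formula: '", x[todo[i]], "'")
      el <- sub("[0-9]*$", "", tk)
      n <- sub("^[A-Za-z]+", "", tk)
      n <- ifelse(nzchar(n), as.integer(n), 1L)
      foreign <- setdiff(el, .ELEMENTS)
      if (length(foreign)) {
        if (strict)
          stop("unsupported element(s) ", paste(foreign, collapse = ", "),
               " in formula '", x[todo[i]], "'; only C,H,N,O,S,P are ",
               "supported (strict = TRUE)")
        keep <- el %in% .ELEMENTS
        el <- el[keep]; n <- n[keep]
        warning("ignoring unsupported element(s) in formula '",
                x[todo[i]], "'")
      }
      cnt <- setNames(integer(length(.ELEMENTS)), .ELEMENTS)
      for (j in seq_along(el)) cnt[el[j]] <- cnt[el[j]] + n[j]
      out[todo[i], ] <- cnt
    }
  }
  as.data.frame(out)
}

#' Write element counts as a Hill-order formula string
#'
#' Carbon first, hydrogen second, remaining elements alphabetically
#' (N, O, P, S); a count of 1 is written without a number, zero counts are
#' omitted.
#'
#' @param C,H,N,O,S,P integer vectors of element counts (recycled).
#' @return character vector; `NA` where `C` is `NA`.
#' @examples
#' formulaString(C = 6, H = 12, O = 6)  # "C6H12O6"
#' @export
formulaString <- function(C, H, N = 0, O = 0, S = 0, P = 0) {
  cnt <- cbind(C = C, H = H, N = N, O = O, P = P, S = S)
  apply(cnt, 1L, function(v) {
    if (anyNA(v[c("C", "H")])) return(NA_character_)
    v[is.na(v)] <- 0
    parts <- vapply(names(v), function(el) {
      if (v[[el]] == 0) "" else if (v[[el]] == 1) el
      else paste0(el, v[[el]])
    }, "")
    paste(parts, collapse = "")
  })
}

#' Monoisotopic mass from element counts
#'
#' Neutral monoisotopic mass (Da) computed from the lightest-isotope masses
#' of C, H, N, O, S, P.
#'
#' @inheritParams formulaString
#' @return numeric vector of masses (Da); `NA` where counts are `NA`.
#' @export
monoisotopicMass <- function(C, H, N = 0, O = 0, S = 0, P = 0) {
  cnt <- cbind(C = C, H = H, N = N, O = O, S = S, P = P)
  as.numeric(cnt %*% .MONO_MASS[colnames(cnt)])
}
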