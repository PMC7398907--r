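#' Parse an elemental formula string
#'
#' Parses a Hill-style elemental formula (e.g. `"C8H14ClN5"`) into a named
#' vector of atom counts. The generic-group wildcards `R`, `X` and `*` that
#' appear in lipid and polymer formulas of automatically reconstructed models
#' are tolerated: they contribute no atoms but set the `wildcard` attribute,
#' which downstream balance audits use to move a reaction from *violations*
#' to *skipped*.
#'
#' @param formula A single formula string. `""` and `NA` parse to an empty
#'   tally flagged with the `empty` attribute.
#'
#' @return A named numeric vector of atom counts with attributes
#'   `wildcard` (logical) and `empty` (logical).
#'
#' @examples
#' parse_formula("C8H14ClN5")   # atrazine
#' parse_formula("C6H9N3O2")    # L-histidine
#' attr(parse_formula("C39H72O5R"), "wildcard")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L || !is.character(formula)) {
    abort("`formula` must be a single character string.")
  }
  if (is.na(formula) || !nzchar(trimws(formula))) {
    return(structure(setNames(numeric(0), character(0)),
                     wildcard = FALSE, empty = TRUE))
  }
  s <- trimws(formula)
  counts <- numeric(0)
  wildcard <- FALSE
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    rest <- substr(s, i, n)
    m <- regmatches(rest, regexpr("^([A-Z][a-z]?|\\*)([0-9]+(\\.[0-9]+)?)?", rest))
    if (length(m) == 0L || !nzchar(m)) {
      abort(sprintf("Cannot parse formula '%s' at position %d ('%s').",
                    s, i, substr(s, i, i)))
    }
    elem <- sub("^([A-Z][a-z]?|\\*).*$", "\\1", m)
    num <- sub("^([A-Z][a-z]?|\\*)", "", m)
    cnt <- if (nzchar(num)) as.numeric(num) else 1
    if (elem %in% c("R", "X", "*")) {
      wildcard <- TRUE
    } else {
      cur <- if (elem %in% names(counts)) counts[[elem]] else 0
      counts[elem] <- cur + cnt
    }
    i <- i + nchar(m)
  }
  structure(counts, wildcard = wildcard, empty = FALSE)
}

#' Carbon and nitrogen atom counts of a compound
#'
#' The C:N ratio of a media supplement is a first-order indicator of its
#' growth-support potential when the compound serves as a combined carbon and
#' nitrogen source (L-isoleucine 6:1, L-histidine 6:3, L-methionine 5:1).
#'
#' @param formula Elemental formula string.
#' @return A tibble with columns `carbon` and `nitrogen`.
#' @examples
#' cn_ratio("C6H13NO2")  # L-isoleucine: 6 C, 1 N
#' @export
cn_ratio <- function(formula) {
  counts <- parse_formula(formula)
  atom <- function(el) if (el %in% names(counts)) counts[[el]] else 0
  tibble(carbon = atom("C"), nitrogen = atom("N"))
}

# Molecular weight from a formula, standard atomic weights.
formula_weight <- function(formula) {
  counts <- parse_formula(formula)
  if (attr(counts, "wildcard")) {
    abort("Cannot compute a molecular weight for a wildcard formula.")
  }
  w <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
         S = 32.06, Cl = 35.45, K = 39.098, Na = 22.99, Mg = 24.305,
         Ca = 40.078, Fe = 55.845, Mn = 54.938, Zn = 65.38, Cu = 63.546)
  unknown <- setdiff(names(counts), names(w))
  if (length(unknown) > 0L) {
    abort(sprintf("No atomic weight for element(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  sum(counts * w[names(counts)])
}
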