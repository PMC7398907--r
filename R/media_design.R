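#' Single-supplement growth screen
#'
#' For each candidate exchange, solves FBA on the base medium plus that one
#' supplement and records the optimal biomass flux. Because adding an uptake
#' allowance only relaxes the LP, a supplement can never reduce the optimum
#' below the base-medium value. Results are sorted by descending growth.
#'
#' @param model A `metabolic_model`.
#' @param base_media The base medium (e.g. MMM + atrazine).
#' @param candidates Character vector of candidate exchange ids.
#' @param supplement_bound Shared uptake bound applied to each candidate
#'   (default 10), unless `candidate_bounds` provides per-candidate values.
#' @param candidate_bounds Optional named numeric vector of per-candidate
#'   uptake bounds.
#' @return A tibble of class `pa_screen` with columns `exchange`, `mu`,
#'   `carbon`, `nitrogen` (atom counts of the supplemented species; NA when
#'   it has no formula), plus attribute `base_mu`.
#' @examples
#' toy <- make_toy_model("TOY-1")
#' supplement_screen(toy, media(c(EX_glc = 10)), "EX_nh4")
#' @export
supplement_screen <- function(model, base_media, candidates,
                              supplement_bound = 10,
                              candidate_bounds = NULL) {
  validate_model(model)
  idx <- reaction_index(model, candidates)
  not_ex <- model$reactions$rtype[idx] != "exchange"
  if (any(not_ex)) {
    abort(sprintf("Candidate(s) not exchange reactions: %s.",
                  paste(candidates[not_ex], collapse = ", ")))
  }
  base_media <- as_media(base_media)
  base_mu <- solve_fba(model, base_media)$objective_value
  comp_formula <- function(ex) {
    j <- reaction_index(model, ex)
    met <- names(model$reactions$stoichiometry[[j]])[1]
    model$metabolites$formula[model$metabolites$id == met]
  }
  rows <- map(candidates, function(ex) {
    b <- if (!is.null(candidate_bounds) && ex %in% names(candidate_bounds)) {
      candidate_bounds[[ex]]
    } else {
      supplement_bound
    }
    mu <- solve_fba(model, media_with(base_media, setNames(b, ex)))$objective_value
    cn <- cn_ratio(comp_formula(ex))
    tibble(exchange = ex, mu = mu, carbon = cn$carbon, nitrogen = cn$nitrogen)
  })
  out <- arrange(bind_rows(rows), desc(.data$mu))
  structure(out, class = c("pa_screen", class(out)), base_mu = base_mu)
}

#' Classify screened supplements as high / moderate / low stimulators
#'
#' Deterministic cutoffs relative to the screen maximum: `high` at or above
#' 66% of the maximum, `low` below 25%, `moderate` in between. The
#' classification is scale-invariant in the growth values.
#'
#' @param result A `pa_screen` (or any tibble with `exchange` and `mu`).
#' @param high_frac,low_frac Cutoff fractions of the screen maximum.
#' @return The input with a `class` column (factor high/moderate/low).
#' @examples
#' screen <- tibble::tibble(exchange = c("ILE", "HIS", "MET", "TOP"),
#'                          mu = c(11.3, 7.4, 1.4, 13))
#' classify_supplements(screen)
#' @export
classify_supplements <- function(result, high_frac = 0.66, low_frac = 0.25) {
  if (nrow(result) == 0L) abort("Empty screen result.")
  mx <- max(result$mu)
  rel <- if (mx > 0) result$mu / mx else rep(1, nrow(result))
  cls <- ifelse(rel >= high_frac, "high",
                ifelse(rel < low_frac, "low", "moderate"))
  result$class <- factor(cls, levels = c("high", "moderate", "low"))
  result
}

#' Growth surface over a carbon-by-nitrogen uptake gradient
#'
#' Computes the FBA optimum on every grid point of two exchange-uptake
#' gradients layered on a base medium (the in-silico analogue of growth
#' surfaces over, e.g., glucose-by-ammonium availability). By LP
#' monotonicity the surface is non-decreasing along each axis.
#'
#' @param model A `metabolic_model`.
#' @param base_media Base medium.
#' @param source1,source2 Exchange ids of the two gradient axes.
#' @param grid1,grid2 Ascending non-negative uptake-bound grids.
#' @return A tibble of class `pa_gradient` with columns `bound1`, `bound2`,
#'   `mu` and attributes `source1`, `source2`.
#' @examples
#' gradient_scan(make_toy_model("TOY-1"), media(), "EX_glc", "EX_nh4",
#'               0:3, 0:3)
#' @export
gradient_scan <- function(model, base_media, source1, source2, grid1, grid2) {
  if (any(grid1 < 0) || any(grid2 < 0) ||
      is.unsorted(grid1) || is.unsorted(grid2)) {
    abort("Grids must be non-negative and ascending.")
  }
  base_media <- as_media(base_media)
  grid <- tidyr::expand_grid(bound1 = grid1, bound2 = grid2)
  grid$mu <- map_dbl(seq_len(nrow(grid)), function(i) {
    m <- media_with(base_media, setNames(c(grid$bound1[i], grid$bound2[i]),
                                         c(source1, source2)))
    solve_fba(model, m)$objective_value
  })
  structure(grid, class = c("pa_gradient", class(grid)),
            source1 = source1, source2 = source2)
}

#' Equimolar-nitrogen dose of a supplement
#'
#' Computes the concentration of a target compound that delivers the same
#' molar nitrogen as a reference solution — the arithmetic used to design
#' media in which each supplement matches the nitrogen content of 30 mg/l
#' atrazine:
#' `dose = conc_ref / MW_ref * (N_ref / N_target) * MW_target`.
#'
#' @param reference A list/row with `formula`, `mw` (g/mol) and `conc`
#'   (mg/l); see [compound()].
#' @param target A list/row with `formula` and `mw`.
#' @param digits Rounding of the reported dose (default nearest integer,
#'   matching printed amino-acid/salt doses; use 1 for liquid amines).
#' @return A one-row tibble with `dose` (rounded) and `dose_exact` (mg/l).
#' @examples
#' atz <- compound("C8H14ClN5", mw = 215.68, conc = 30)
#' equimolar_nitrogen_dose(atz, compound("C6H9N3O2", mw = 155.15))  # 36 mg/l
#' @export
equimolar_nitrogen_dose <- function(reference, target, digits = 0) {
  n_ref <- cn_ratio(reference$formula)$nitrogen
  n_tgt <- cn_ratio(target$formula)$nitrogen
  if (n_ref == 0) abort("Reference compound contains no nitrogen.")
  if (n_tgt == 0) abort("Cannot match nitrogen: target contains no nitrogen.")
  exact <- reference$conc / reference$mw * (n_ref / n_tgt) * target$mw
  tibble(dose = round(exact, digits), dose_exact = exact)
}

#' Describe a compound for dose arithmetic
#'
#' @param formula Elemental formula.
#' @param mw Molecular weight, g/mol; computed from the formula when omitted.
#' @param conc Optional concentration, mg/l.
#' @return A list with `formula`, `mw`, `conc`.
#' @export
compound <- function(formula, mw = NULL, conc = NA_real_) {
  list(formula = formula, mw = mw %||% formula_weight(formula), conc = conc)
}
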