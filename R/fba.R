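#' Flux balance analysis
#'
#' Maximises the biomass objective subject to the steady-state constraint
#' `S v = 0` and the flux bounds that result from applying `media` to the
#' model. Only the objective value is contract-stable: the flux vector at a
#' degenerate optimum is one of possibly many optimal vertices (use
#' [run_fva()] for the stable per-reaction ranges).
#'
#' @param model A `metabolic_model`.
#' @param media Optional medium (see [media()]); when `NULL` the model's
#'   current bounds are used as-is.
#' @param tol LP tolerance.
#' @return An object of class `pa_fba`: list with `objective_value` (biomass
#'   flux, h^-1), `fluxes` (named numeric), `status`, `tol`.
#' @examples
#' sol <- solve_fba(make_toy_model("TOY-1"), c(EX_glc = 10, EX_nh4 = 10))
#' sol$objective_value  # 10: glucose-limited
#' @export
solve_fba <- function(model, media = NULL, tol = 1e-9) {
  validate_model(model)
  if (!is.null(media)) model <- apply_media(model, media)
  S <- steady_state_matrix(model)
  n <- nrow(model$reactions)
  obj <- as.numeric(model$reactions$id == model$objective_id)
  res <- lp_maximize(obj, S, model$reactions$lower_bound,
                     model$reactions$upper_bound, tol = tol)
  fluxes <- if (res$status == "optimal") {
    setNames(res$solution, model$reactions$id)
  } else {
    setNames(rep(0, n), model$reactions$id)
  }
  structure(
    list(objective_value = if (res$status == "optimal") res$value else 0,
         fluxes = fluxes, status = res$status, tol = tol,
         objective_id = model$objective_id),
    class = "pa_fba"
  )
}

#' @export
print.pa_fba <- function(x, ...) {
  cat(sprintf("<pa_fba> status: %s, objective (%s): %.6g h^-1\n",
              x$status, x$objective_id, x$objective_value))
  invisible(x)
}

#' @method tidy pa_fba
#' @export
tidy.pa_fba <- function(x, ...) {
  tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' @method glance pa_fba
#' @export
glance.pa_fba <- function(x, ...) {
  tibble(objective_value = x$objective_value, status = x$status, tol = x$tol)
}

#' Flux variability analysis
#'
#' With the biomass flux constrained to at least `objective_fraction` of its
#' optimum, minimises and maximises each requested reaction flux. The
#' original FBA flux always lies inside the reported range. Fraction 0 yields
#' plain bounds propagation (the objective is unconstrained).
#'
#' @param model A `metabolic_model`.
#' @param media Optional medium.
#' @param reaction_ids Reactions to scan; defaults to all.
#' @param objective_fraction Fraction of the FBA optimum to enforce, in
#'   `[0, 1]`.
#' @param tol LP tolerance (also the slack applied below the enforced
#'   optimum to avoid knife-edge infeasibility).
#' @return A tibble of class `pa_fva` with columns `reaction`, `min`, `max`,
#'   and attribute `objective_value`.
#' @examples
#' run_fva(make_toy_model("TOY-1"), c(EX_glc = 10, EX_nh4 = 10),
#'         reaction_ids = "EX_glc")
#' @export
run_fva <- function(model, media = NULL, reaction_ids = NULL,
                    objective_fraction = 1, tol = 1e-9) {
  if (objective_fraction < 0 || objective_fraction > 1) {
    abort("`objective_fraction` must be in [0, 1].")
  }
  validate_model(model)
  if (!is.null(media)) model <- apply_media(model, media)
  if (is.null(reaction_ids)) reaction_ids <- model$reactions$id
  reaction_index(model, reaction_ids)

  base <- solve_fba(model, tol = tol)
  if (base$status != "optimal") {
    abort(sprintf("FBA is %s; cannot run FVA.", base$status))
  }
  mu <- base$objective_value
  if (objective_fraction > 0) {
    oi <- reaction_index(model, model$objective_id)
    floor_mu <- objective_fraction * mu - 10 * tol
    model$reactions$lower_bound[oi] <-
      max(model$reactions$lower_bound[oi], floor_mu)
  }
  S <- steady_state_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- nrow(model$reactions)
  ranges <- map(reaction_ids, function(id) {
    j <- reaction_index(model, id)
    e <- numeric(n); e[j] <- 1
    hi <- lp_maximize(e, S, lb, ub, tol = tol)
    lo <- lp_maximize(-e, S, lb, ub, tol = tol)
    if (hi$status != "optimal" || lo$status != "optimal") {
      abort(sprintf(
        "FVA infeasible for '%s' at objective fraction %.3g.", id,
        objective_fraction))
    }
    c(min = -lo$value, max = hi$value)
  })
  out <- tibble(
    reaction = reaction_ids,
    min = map_dbl(ranges, "min"),
    max = map_dbl(ranges, "max")
  )
  structure(out, class = c("pa_fva", class(out)), objective_value = mu)
}

#' @method tidy pa_fva
#' @export
tidy.pa_fva <- function(x, ...) as_tibble(x)

#' Degradation capacity of a substrate at the growth optimum
#'
#' After fixing biomass at its maximum, reports the feasible range of uptake
#' of a target exchange (the FVA-based estimate of degradation rate, e.g.
#' atrazine uptake at optimal growth). Returned as uptake magnitudes.
#'
#' @param model A `metabolic_model`.
#' @param media Medium in which the target exchange is open.
#' @param target_exchange Exchange reaction id.
#' @return A one-row tibble with `min_uptake`, `max_uptake` and
#'   `objective_value`.
#' @export
degradation_capacity <- function(model, media, target_exchange) {
  j <- reaction_index(model, target_exchange)
  if (model$reactions$rtype[j] != "exchange") {
    abort(sprintf("'%s' is not an exchange reaction.", target_exchange))
  }
  fva <- run_fva(model, media, reaction_ids = target_exchange,
                 objective_fraction = 1)
  # uptake is negative flux; magnitudes swap min/max
  tibble(
    exchange = target_exchange,
    min_uptake = max(0, -fva$max[1]),
    max_uptake = max(0, -fva$min[1]),
    objective_value = attr(fva, "objective_value")
  )
}
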