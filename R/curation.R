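#' Elemental and charge balance of one reaction
#'
#' Sums `coefficient x atom count` over all participants. A balanced reaction
#' tallies zero for every element. Exchange and biomass pseudo-reactions are
#' exempt (they are unbalanced by definition) and are reported as
#' not-applicable. Charge is tallied only when every participant carries a
#' charge annotation. Participants with wildcard (R/X/*) formulas make the
#' tally a skip, not a violation.
#'
#' @param reaction One row of a model's reaction tibble (or a list with
#'   `id`, `stoichiometry`, `rtype`).
#' @param metabolites The model's metabolite tibble (formula/charge lookup).
#' @return A list of class `element_tally`: `elements` (named numeric
#'   imbalances, zero entries dropped), `charge_imbalance`, `applicable`,
#'   `skipped`, `balanced`.
#' @export
check_reaction_balance <- function(reaction, metabolites) {
  if (is.data.frame(reaction)) {
    reaction <- list(id = reaction$id[1],
                     stoichiometry = reaction$stoichiometry[[1]],
                     rtype = reaction$rtype[1])
  }
  out <- list(id = reaction$id, elements = numeric(0),
              charge_imbalance = NA_real_, applicable = TRUE,
              skipped = FALSE, balanced = NA)
  if (reaction$rtype %in% c("exchange", "biomass")) {
    out$applicable <- FALSE
    return(structure(out, class = "element_tally"))
  }
  st <- reaction$stoichiometry
  idx <- match(names(st), metabolites$id)
  if (any(is.na(idx))) {
    abort(sprintf("Reaction '%s' references unknown metabolite(s): %s.",
                  reaction$id,
                  paste(names(st)[is.na(idx)], collapse = ", ")))
  }
  tally <- numeric(0)
  wildcard <- FALSE
  for (k in seq_along(st)) {
    f <- metabolites$formula[idx[k]]
    counts <- parse_formula(f)
    if (attr(counts, "empty")) {
      abort(sprintf("Metabolite '%s' in reaction '%s' has no formula.",
                    names(st)[k], reaction$id))
    }
    if (attr(counts, "wildcard")) wildcard <- TRUE
    for (el in names(counts)) {
      cur <- if (el %in% names(tally)) tally[[el]] else 0
      tally[el] <- cur + st[[k]] * counts[[el]]
    }
  }
  charges <- metabolites$charge[idx]
  if (!anyNA(charges)) {
    out$charge_imbalance <- sum(st * charges)
  }
  tol <- 1e-9
  out$elements <- tally[abs(tally) > tol]
  out$skipped <- wildcard
  out$balanced <- !wildcard && length(out$elements) == 0L &&
    (is.na(out$charge_imbalance) || abs(out$charge_imbalance) < tol)
  structure(out, class = "element_tally")
}

#' Audit a whole model for stoichiometric balance
#'
#' Every non-exchange, non-biomass reaction is checked with
#' [check_reaction_balance()]; reactions containing wildcard formulas are
#' listed under `skipped` rather than `violations`.
#'
#' @param model A `metabolic_model`.
#' @return A list of class `audit_report`: `passed`, `violations` (tibble of
#'   reaction id + imbalance description), `skipped` (reaction ids).
#' @examples
#' audit_model_balance(make_toy_model("TOY-2"))$passed
#' @export
audit_model_balance <- function(model) {
  validate_model(model)
  violations <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(model$reactions))) {
    tl <- check_reaction_balance(model$reactions[i, ], model$metabolites)
    if (!tl$applicable) next
    if (tl$skipped) {
      skipped <- c(skipped, model$reactions$id[i])
    } else if (!tl$balanced) {
      violations[[length(violations) + 1L]] <- tibble(
        reaction = model$reactions$id[i],
        imbalance = paste(
          c(sprintf("%s: %+g", names(tl$elements), tl$elements),
            if (!is.na(tl$charge_imbalance) &&
                abs(tl$charge_imbalance) > 1e-9)
              sprintf("charge: %+g", tl$charge_imbalance)),
          collapse = ", ")
      )
    }
  }
  violations <- if (length(violations) > 0L) bind_rows(violations) else
    tibble(reaction = character(0), imbalance = character(0))
  structure(list(passed = nrow(violations) == 0L,
                 violations = violations, skipped = skipped),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("<audit_report> %s: %d violation(s), %d skipped\n",
              if (x$passed) "PASSED" else "FAILED",
              nrow(x$violations), length(x$skipped)))
  if (nrow(x$violations) > 0L) print(x$violations)
  invisible(x)
}

#' Blocked-exchange (futile energy loop) audit
#'
#' Closes every exchange reaction in both directions and maximises the
#' biomass objective (and an optional ATP-hydrolysis probe reaction). Any
#' flux above tolerance with all external fluxes blocked indicates a futile
#' or erroneously energy-generating loop in the network.
#'
#' @param model A `metabolic_model`.
#' @param atp_probe Optional id of an ATP-hydrolysis reaction to maximise as
#'   a second probe.
#' @param tol Pass tolerance on the maxima.
#' @return A list with `biomass_flux`, `atp_yield` (NA when no probe),
#'   `passed` and `status`.
#' @examples
#' blocked_exchange_audit(make_toy_model("TOY-1"))$passed
#' @export
blocked_exchange_audit <- function(model, atp_probe = NULL, tol = 1e-6) {
  validate_model(model)
  closed <- model
  is_ex <- closed$reactions$rtype == "exchange"
  closed$reactions$lower_bound[is_ex] <- 0
  closed$reactions$upper_bound[is_ex] <- 0
  sol <- solve_fba(closed)
  biomass <- sol$objective_value
  status <- sol$status
  atp <- NA_real_
  if (!is.null(atp_probe)) {
    j <- reaction_index(closed, atp_probe)
    S <- steady_state_matrix(closed)
    e <- numeric(nrow(closed$reactions)); e[j] <- 1
    res <- lp_maximize(e, S, closed$reactions$lower_bound,
                       closed$reactions$upper_bound)
    atp <- if (res$status == "optimal") res$value else NA_real_
    if (res$status != "optimal") status <- res$status
  }
  passed <- status == "optimal" && biomass <= tol &&
    (is.na(atp) || atp <= tol)
  list(biomass_flux = biomass, atp_yield = atp, passed = passed,
       status = status)
}

#' Carbon / nitrogen requirement audit
#'
#' Evaluates FBA growth on the full medium, the medium with every listed
#' carbon-source exchange removed, and the medium with every nitrogen-source
#' exchange removed. A well-curated heterotroph model grows only when both
#' element sources are supplied.
#'
#' @param model A `metabolic_model`.
#' @param media The full medium.
#' @param carbon_sources,nitrogen_sources Exchange ids of the medium's C and
#'   N sources.
#' @param tol Growth tolerance.
#' @return A tibble with columns `condition`
#'   (`"full"`, `"no_carbon"`, `"no_nitrogen"`), `biomass_flux`, and
#'   attribute `requirement_satisfied`.
#' @export
nutrient_requirement_audit <- function(model, media, carbon_sources,
                                       nitrogen_sources, tol = 1e-6) {
  media <- as_media(media)
  drop_sources <- function(m, ids) media(as_tibble(m)[!m$exchange %in% ids, ])
  mu <- function(m) solve_fba(model, m)$objective_value
  out <- tibble(
    condition = c("full", "no_carbon", "no_nitrogen"),
    biomass_flux = c(mu(media),
                     mu(drop_sources(media, carbon_sources)),
                     mu(drop_sources(media, nitrogen_sources)))
  )
  attr(out, "requirement_satisfied") <-
    out$biomass_flux[1] > tol && all(out$biomass_flux[2:3] <= tol)
  out
}

#' Reaction directionality report
#'
#' Report-only curation aid: lists reversible reactions whose reverse
#' direction is never used at the growth optimum (FVA minimum >= -tol), i.e.
#' candidates for tightening to irreversible. No bounds are changed.
#'
#' @param model A `metabolic_model`.
#' @param media Medium for the reference optimum.
#' @param tol Flux tolerance.
#' @return A tibble with `reaction`, `min`, `max`, `reverse_unused`.
#' @export
directionality_report <- function(model, media = NULL, tol = 1e-6) {
  rev_ids <- model$reactions$id[model$reactions$lower_bound < 0 &
                                  model$reactions$rtype != "exchange"]
  if (length(rev_ids) == 0L) {
    return(tibble(reaction = character(0), min = numeric(0),
                  max = numeric(0), reverse_unused = logical(0)))
  }
  fva <- run_fva(model, media, reaction_ids = rev_ids, objective_fraction = 1)
  mutate(as_tibble(fva), reverse_unused = .data$min >= -tol)
}
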