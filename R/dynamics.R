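#' Configuration of a dynamic growth/degradation simulation
#'
#' The time-stepped simulation works on four assumptions: finite
#' starting pools of media components (default 50 units each), a per-cell
#' uptake cap (default 1 unit of each metabolite per biomass unit per tick),
#' pools updated each tick from the realized exchange fluxes, and biomass
#' updated from the realized growth rate. Units are the dimensionless
#' "units" of the source protocol; a scale factor to mmol or mg/l is the
#' caller's concern.
#'
#' @param initial_pools Named numeric vector: exchange id -> starting amount.
#' @param initial_biomass Starting biomass (default one cell-unit).
#' @param dt Time tick, h.
#' @param uptake_cap Max uptake per biomass unit per tick.
#' @param max_cycles Hard iteration limit.
#' @param stall_tol Relative biomass increase below which the run stops
#'   ("time cycles did not lead to an increase in biomass").
#' @param exponential_update Use `X * exp(mu dt)` instead of the default
#'   forward-Euler `X * (1 + mu dt)`.
#' @return A list of class `dynamic_config`.
#' @export
dynamic_config <- function(initial_pools, initial_biomass = 1, dt = 1,
                           uptake_cap = 1, max_cycles = 1000L,
                           stall_tol = 1e-6, exponential_update = FALSE) {
  stopifnot(initial_biomass > 0, dt > 0, uptake_cap > 0, max_cycles >= 1,
            stall_tol > 0, stall_tol < 1)
  pools <- if (is.data.frame(initial_pools)) {
    setNames(initial_pools$amount, initial_pools$exchange)
  } else {
    initial_pools
  }
  if (any(pools < 0)) abort("Initial pools must be non-negative.")
  structure(list(initial_pools = pools, initial_biomass = initial_biomass,
                 dt = dt, uptake_cap = uptake_cap,
                 max_cycles = as.integer(max_cycles), stall_tol = stall_tol,
                 exponential_update = exponential_update),
            class = "dynamic_config")
}

#' Per-tick uptake bounds from pools and population size
#'
#' For each pooled exchange the uptake bound is
#' `min(uptake_cap, pool / (X * dt))`: a cell can take at most the cap, and
#' the whole population can never overdraw the pool. Exhausted pools give a
#' zero bound.
#'
#' @param pools Named numeric vector of current pool amounts.
#' @param X Current biomass (> 0).
#' @param config A `dynamic_config`.
#' @return A `pa_media` of uptake bounds.
#' @examples
#' compute_uptake_bounds(c(EX_glc = 50), 1, dynamic_config(c(EX_glc = 50)))
#' @export
compute_uptake_bounds <- function(pools, X, config) {
  if (X <= 0) abort("Biomass must be positive.")
  if (any(pools < -1e-9)) abort("Negative pool amount (internal invariant).")
  pools <- pmax(pools, 0)
  bound <- pmin(config$uptake_cap, pools / (X * config$dt))
  media(setNames(bound, names(pools)), name = "dynamic-tick")
}

#' Time-stepped growth and substrate-depletion simulation
#'
#' Iterates: set exchange uptake bounds from the current pools via
#' [compute_uptake_bounds()], solve FBA, update pools from the realized
#' exchange fluxes (`pool <- pool + v_ex * X * dt`; uptake is negative flux,
#' secretion positive and accumulates for possible later re-consumption),
#' and update biomass (`X <- X * (1 + mu * dt)` by default). Exchanges not
#' in the pools are closed for uptake but left open for secretion; a
#' secreted metabolite gets a pool that starts at 0. The run stops when the
#' relative biomass increase falls below `stall_tol` or after `max_cycles`.
#' An infeasible tick records `mu = 0` and then stalls out.
#'
#' @param model A `metabolic_model`.
#' @param config A `dynamic_config` (its `initial_pools` names must be
#'   exchange reactions of the model).
#' @return An object of class `pa_trajectory`: list with `states` (tibble:
#'   `time`, `biomass`, `mu`), `pools` (tibble: `time`, `exchange`,
#'   `amount`) and `fluxes` (tibble: `time`, `exchange`, `flux`).
#' @examples
#' traj <- simulate_timecourse(
#'   make_toy_model("TOY-1"),
#'   dynamic_config(c(EX_glc = 50, EX_nh4 = 50)))
#' tail(traj$states, 1)$biomass  # 51: all 50 glucose units fixed at yield 1
#' @export
simulate_timecourse <- function(model, config) {
  validate_model(model)
  reaction_index(model, names(config$initial_pools))
  ex_ids <- exchange_ids(model)
  bad <- setdiff(names(config$initial_pools), ex_ids)
  if (length(bad) > 0L) {
    abort(sprintf("Pool id(s) not exchange reactions: %s.",
                  paste(bad, collapse = ", ")))
  }
  pools <- config$initial_pools
  X <- config$initial_biomass
  dt <- config$dt
  t <- 0
  states <- list()
  pool_rows <- list()
  flux_rows <- list()
  for (cycle in seq_len(config$max_cycles)) {
    bounds <- compute_uptake_bounds(pools, X, config)
    sol <- solve_fba(model, bounds)
    mu <- if (sol$status == "optimal") sol$objective_value else 0
    v_ex <- sol$fluxes[ex_ids]
    states[[cycle]] <- tibble(time = t, biomass = X, mu = mu)
    pool_rows[[cycle]] <- tibble(time = t, exchange = names(pools),
                                 amount = unname(pools))
    flux_rows[[cycle]] <- tibble(time = t, exchange = ex_ids,
                                 flux = unname(v_ex))
    # pool update: uptake (v < 0) drains, secretion (v > 0) accumulates
    delta <- v_ex * X * dt
    for (ex in ex_ids) {
      d <- delta[[ex]]
      if (ex %in% names(pools)) {
        pools[[ex]] <- max(0, pools[[ex]] + d)
      } else if (d > 1e-12) {
        pools[[ex]] <- d
      }
    }
    X_new <- if (config$exponential_update) X * exp(mu * dt) else
      X * (1 + mu * dt)
    stalled <- (X_new - X) / X < config$stall_tol
    X <- X_new
    t <- t + dt
    if (stalled) break
  }
  structure(list(states = bind_rows(states),
                 pools = bind_rows(pool_rows),
                 fluxes = bind_rows(flux_rows),
                 config = config),
            class = "pa_trajectory")
}

#' @export
print.pa_trajectory <- function(x, ...) {
  ns <- nrow(x$states)
  cat(sprintf("<pa_trajectory> %d ticks, final biomass %.4g\n",
              ns, x$states$biomass[ns]))
  invisible(x)
}

#' @method tidy pa_trajectory
#' @export
tidy.pa_trajectory <- function(x, ...) {
  tidyr::pivot_wider(x$pools, names_from = "exchange",
                     values_from = "amount") |>
    left_join(x$states, by = "time") |>
    select("time", "biomass", "mu", dplyr::everything())
}

#' Substrate depletion curve
#'
#' Extracts the amount of a tracked substrate remaining in the medium at
#' each tick — the simulated analogue of measuring residual atrazine after
#' each time cycle. The series is monotone non-increasing for a substrate
#' that is only consumed.
#'
#' @param trajectory A `pa_trajectory`.
#' @param target Exchange id tracked in the pools.
#' @return A tibble with `time` and `amount`.
#' @export
degradation_curve <- function(trajectory, target) {
  hits <- trajectory$pools[trajectory$pools$exchange == target, ]
  if (nrow(hits) == 0L) {
    abort(sprintf("'%s' is not tracked in the trajectory pools.", target))
  }
  select(arrange(hits, .data$time), "time", "amount")
}

#' Write a trajectory as TSV (one row per tick, pools as columns)
#'
#' @param trajectory A `pa_trajectory`.
#' @param path Output file.
#' @export
write_trajectory <- function(trajectory, path) {
  readr::write_tsv(tidy(trajectory), path)
  invisible(path)
}
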