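#' Read a model from delimited tables
#'
#' Two tab-delimited tables describe a model. `metabolites_path` must have
#' columns `id`, `name`, `formula`, `charge`, `compartment`, `boundary`.
#' `reactions_path` must have `id`, `name`, `stoichiometry`, `lower_bound`,
#' `upper_bound`, `gpr`, `rtype`, with stoichiometry encoded as
#' `"met:coef; met:coef"` (negative = substrate). The objective defaults to
#' the single reaction with `rtype == "biomass"`.
#'
#' @param reactions_path,metabolites_path File paths.
#' @param objective_id Override for the objective reaction id.
#' @return A `metabolic_model`.
#' @export
read_model_tables <- function(reactions_path, metabolites_path,
                              objective_id = NULL) {
  mets <- readr::read_tsv(metabolites_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            formula = readr::col_character(),
                            .default = readr::col_guess()))
  need_m <- c("id", "compartment")
  miss <- setdiff(need_m, names(mets))
  if (length(miss) > 0L) {
    abort(sprintf("Metabolite table missing column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  rx <- readr::read_tsv(reactions_path, show_col_types = FALSE)
  need_r <- c("id", "stoichiometry")
  miss <- setdiff(need_r, names(rx))
  if (length(miss) > 0L) {
    abort(sprintf("Reaction table missing column(s): %s.",
                  paste(miss, collapse = ", ")))
  }
  rx$stoichiometry <- map(rx$stoichiometry, parse_stoich)
  unknown <- setdiff(unique(unlist(map(rx$stoichiometry, names))), mets$id)
  if (length(unknown) > 0L) {
    offenders <- rx$id[map_lgl(rx$stoichiometry,
                               function(s) any(names(s) %in% unknown))]
    abort(sprintf("Reaction(s) %s reference unknown metabolite id(s): %s.",
                  paste(offenders, collapse = ", "),
                  paste(unknown, collapse = ", ")))
  }
  if (is.null(objective_id)) {
    if (!"rtype" %in% names(rx)) {
      abort("No objective: supply `objective_id` or an `rtype` column.")
    }
    bio <- rx$id[!is.na(rx$rtype) & rx$rtype == "biomass"]
    if (length(bio) != 1L) {
      abort(sprintf("No objective: found %d biomass reactions.", length(bio)))
    }
    objective_id <- bio
  }
  metabolic_model(mets, rx, objective_id = objective_id)
}

#' Write a model as delimited tables
#'
#' Inverse of [read_model_tables()]; the pair round-trips losslessly.
#'
#' @param model A `metabolic_model`.
#' @param reactions_path,metabolites_path Output paths.
#' @export
write_model_tables <- function(model, reactions_path, metabolites_path) {
  readr::write_tsv(model$metabolites, metabolites_path)
  rx <- mutate(model$reactions,
               stoichiometry = map_chr(.data$stoichiometry, format_stoich))
  readr::write_tsv(rx, reactions_path)
  invisible(reactions_path)
}

format_stoich <- function(st) {
  paste(sprintf("%s:%.10g", names(st), unname(st)), collapse = "; ")
}

parse_stoich <- function(s) {
  parts <- strsplit(trimws(s), ";")[[1]]
  parts <- trimws(parts[nzchar(trimws(parts))])
  if (length(parts) == 0L) return(setNames(numeric(0), character(0)))
  kv <- strsplit(parts, ":")
  bad <- map_lgl(kv, function(p) length(p) != 2L || is.na(suppressWarnings(
    as.numeric(trimws(p[2])))))
  if (any(bad)) {
    abort(sprintf("Cannot parse stoichiometry term(s): %s.",
                  paste(parts[bad], collapse = ", ")))
  }
  setNames(vapply(kv, function(p) as.numeric(trimws(p[2])), numeric(1)),
           vapply(kv, function(p) trimws(p[1]), character(1)))
}
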