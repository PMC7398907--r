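#' Construct a genome-scale metabolic model
#'
#' A metabolic model is a pair of tibbles — metabolites and reactions — plus
#' the id of the biomass objective reaction. Reaction stoichiometries are
#' stored as named numeric vectors in a list column (negative coefficients
#' are substrates). The structure mirrors the usual constraint-based layout:
#' `m` metabolite rows and `n` reaction columns of a stoichiometric matrix
#' `S`, with flux bounds per reaction and a biomass pseudo-reaction whose
#' flux (h^-1) proxies growth rate.
#'
#' Metabolites flagged `boundary = TRUE` (the SBML `boundaryCondition`
#' semantics) appear in `S` but are excluded from the steady-state constraint
#' `S v = 0`; the biomass product species of the toy fixtures is such a sink.
#'
#' @param metabolites A data frame with columns `id`, and optionally `name`,
#'   `formula`, `charge`, `compartment` (`"cytosol"` or `"extracellular"`),
#'   `boundary`.
#' @param reactions A data frame with columns `id`, `stoichiometry` (a list of
#'   named numeric vectors), and optionally `name`, `lower_bound`,
#'   `upper_bound` (mmol gDW^-1 h^-1; defaults -1000/1000 for reversible
#'   entries, 0/1000 where a `reversible` column says `FALSE`), `gpr`, `rtype`
#'   (`"exchange"`, `"transport"`, `"cytosolic"` or `"biomass"`; inferred when
#'   absent).
#' @param objective_id Id of the biomass reaction to maximise.
#'
#' @return An object of class `metabolic_model`.
#' @seealso [make_toy_model()], [read_sbml()], [model_summary()]
#' @export
metabolic_model <- function(metabolites, reactions, objective_id) {
  mets <- as_tibble(metabolites)
  if (!"id" %in% names(mets)) abort("`metabolites` needs an `id` column.")
  mets$id <- as.character(mets$id)
  if (!"name" %in% names(mets)) mets$name <- mets$id
  if (!"formula" %in% names(mets)) mets$formula <- ""
  mets$formula[is.na(mets$formula)] <- ""
  if (!"charge" %in% names(mets)) mets$charge <- NA_integer_
  if (!"compartment" %in% names(mets)) mets$compartment <- "cytosol"
  if (!"boundary" %in% names(mets)) mets$boundary <- FALSE
  mets$boundary[is.na(mets$boundary)] <- FALSE
  mets <- mets[, c("id", "name", "formula", "charge", "compartment", "boundary")]

  rxns <- as_tibble(reactions)
  if (!all(c("id", "stoichiometry") %in% names(rxns))) {
    abort("`reactions` needs `id` and `stoichiometry` columns.")
  }
  rxns$id <- as.character(rxns$id)
  if (!"name" %in% names(rxns)) rxns$name <- rxns$id
  if (!"lower_bound" %in% names(rxns) || !"upper_bound" %in% names(rxns)) {
    rev <- if ("reversible" %in% names(rxns)) rxns$reversible else TRUE
    if (!"lower_bound" %in% names(rxns)) rxns$lower_bound <- ifelse(rev, -1000, 0)
    if (!"upper_bound" %in% names(rxns)) rxns$upper_bound <- 1000
  }
  if (!"gpr" %in% names(rxns)) rxns$gpr <- ""
  rxns$gpr[is.na(rxns$gpr)] <- ""
  if (!"rtype" %in% names(rxns)) rxns$rtype <- NA_character_

  model <- structure(
    list(metabolites = mets, reactions = rxns, objective_id = objective_id),
    class = "metabolic_model"
  )
  model$reactions$rtype <- infer_rtype(model)
  model$reactions <- model$reactions[, c("id", "name", "stoichiometry",
                                         "lower_bound", "upper_bound",
                                         "gpr", "rtype")]
  validate_model(model)
  model
}

# Classify reactions: exchange = single extracellular species; biomass = the
# declared objective; transport = spans compartments; cytosolic otherwise.
# Pre-set rtype values are kept.
infer_rtype <- function(model) {
  comp <- setNames(model$metabolites$compartment, model$metabolites$id)
  rxns <- model$reactions
  vapply(seq_len(nrow(rxns)), function(i) {
    if (!is.na(rxns$rtype[i])) return(rxns$rtype[i])
    if (identical(rxns$id[i], model$objective_id)) return("biomass")
    st <- rxns$stoichiometry[[i]]
    parts <- unname(comp[names(st)])
    if (length(st) == 1L && identical(parts, "extracellular")) return("exchange")
    if (length(unique(parts)) > 1L) return("transport")
    "cytosolic"
  }, character(1))
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, compartment membership, bound ordering
#' (`lower_bound <= upper_bound`), that every metabolite referenced by a
#' reaction is declared, that the objective exists and is the biomass
#' reaction, and that exchange reactions touch exactly one extracellular
#' species. Errors name the offending reactions or metabolites.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly, if valid.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    abort(sprintf("Duplicate metabolite ids: %s.",
                  paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  }
  if (anyDuplicated(rxns$id)) {
    abort(sprintf("Duplicate reaction ids: %s.",
                  paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")))
  }
  bad_comp <- setdiff(unique(mets$compartment), c("cytosol", "extracellular"))
  if (length(bad_comp) > 0L) {
    abort(sprintf("Unknown compartment(s): %s.", paste(bad_comp, collapse = ", ")))
  }
  flipped <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  if (length(flipped) > 0L) {
    abort(sprintf("lower_bound > upper_bound for reaction(s): %s.",
                  paste(flipped, collapse = ", ")))
  }
  referenced <- unique(unlist(lapply(rxns$stoichiometry, names)))
  missing <- setdiff(referenced, mets$id)
  if (length(missing) > 0L) {
    abort(sprintf("Reactions reference undeclared metabolite(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  empty <- vapply(rxns$stoichiometry, length, integer(1)) == 0L
  if (any(empty)) {
    abort(sprintf("Empty stoichiometry for reaction(s): %s.",
                  paste(rxns$id[empty], collapse = ", ")))
  }
  if (!model$objective_id %in% rxns$id) {
    abort(sprintf("Objective reaction '%s' not in model.", model$objective_id))
  }
  if (rxns$rtype[rxns$id == model$objective_id] != "biomass") {
    abort(sprintf("Objective reaction '%s' is not of rtype 'biomass'.",
                  model$objective_id))
  }
  comp <- setNames(mets$compartment, mets$id)
  for (i in which(rxns$rtype == "exchange")) {
    st <- rxns$stoichiometry[[i]]
    if (length(st) != 1L || comp[[names(st)]] != "extracellular") {
      abort(sprintf(
        "Exchange reaction '%s' must touch exactly one extracellular metabolite.",
        rxns$id[i]))
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  s <- model_summary(x)
  cat(sprintf(
    "<metabolic_model> %d metabolites, %d reactions (%d exchange), %d genes\n",
    s$metabolites, s$reactions, s$exchange_reactions, s$genes))
  cat(sprintf("objective: %s\n", x$objective_id))
  invisible(x)
}

#' Summarise a model's network statistics
#'
#' Counts genes (distinct ids parsed from the boolean gene-association
#' strings), reactions, exchange reactions and metabolites — the four
#' headline statistics of a reconstruction.
#'
#' @param model A `metabolic_model`.
#' @return A one-row tibble with columns `genes`, `reactions`,
#'   `exchange_reactions`, `metabolites`.
#' @examples
#' model_summary(make_toy_model("TOY-1"))
#' @export
model_summary <- function(model) {
  validate_model(model)
  tibble(
    genes = length(model_genes(model)),
    reactions = nrow(model$reactions),
    exchange_reactions = sum(model$reactions$rtype == "exchange"),
    metabolites = nrow(model$metabolites)
  )
}

#' Distinct gene ids referenced by a model's gene associations
#'
#' Gene-protein-reaction strings use `and`/`or` and parentheses; only the
#' distinct identifiers are extracted (no boolean evaluation).
#'
#' @param model A `metabolic_model`.
#' @return Character vector of gene ids, sorted.
#' @export
model_genes <- function(model) {
  gprs <- model$reactions$gpr
  gprs <- gprs[nzchar(gprs)]
  if (length(gprs) == 0L) return(character(0))
  toks <- unlist(strsplit(gsub("[()]", " ", gprs), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  sort(unique(toks[!tolower(toks) %in% c("and", "or")]))
}

#' Assemble the stoichiometric matrix
#'
#' Builds the sparse `m x n` matrix `S` whose entry `S[i, j]` is the signed
#' coefficient of metabolite `i` in reaction `j`. Row order follows the
#' metabolite table, column order the reaction table.
#'
#' @param model A `metabolic_model`.
#' @return A `dgCMatrix` with metabolite ids as rownames and reaction ids as
#'   colnames.
#' @examples
#' S <- build_stoichiometric_matrix(make_toy_model("TOY-1"))
#' dim(S)
#' @export
build_stoichiometric_matrix <- function(model) {
  m <- nrow(model$metabolites)
  n <- nrow(model$reactions)
  if (m == 0L || n == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(m, n),
                                dimnames = list(model$metabolites$id,
                                                model$reactions$id)))
  }
  row_of <- setNames(seq_len(m), model$metabolites$id)
  ijx <- lapply(seq_len(n), function(j) {
    st <- model$reactions$stoichiometry[[j]]
    list(i = unname(row_of[names(st)]), j = rep(j, length(st)), x = unname(st))
  })
  Matrix::sparseMatrix(
    i = unlist(lapply(ijx, `[[`, "i")),
    j = unlist(lapply(ijx, `[[`, "j")),
    x = unlist(lapply(ijx, `[[`, "x")),
    dims = c(m, n),
    dimnames = list(model$metabolites$id, model$reactions$id)
  )
}

exchange_ids <- function(model) {
  model$reactions$id[model$reactions$rtype == "exchange"]
}

# Lookup helpers used across modules
reaction_index <- function(model, id) {
  idx <- match(id, model$reactions$id)
  if (any(is.na(idx))) {
    abort(sprintf("Unknown reaction id(s): %s.",
                  paste(id[is.na(idx)], collapse = ", ")))
  }
  idx
}
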