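#' Read a metabolic model from SBML
#'
#' Reads SBML Level 3 with the flux-bounds/objective (`fbc`) extension:
#' bounds are resolved through the global parameter list referenced by
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound`, the objective from the active
#' member of `fbc:listOfObjectives`, gene associations from
#' `fbc:geneProductAssociation` (or a legacy `GENE_ASSOCIATION:` note).
#' A documented legacy fallback covers the ModelSEED dialect: per-reaction
#' kinetic-law parameters named `LOWER_BOUND`/`UPPER_BOUND`, and — when no
#' objective is declared — a single reaction whose id or name matches
#' `biomass` (case-insensitive); zero or several matches raise a "no
#' objective" error rather than guessing. Compartments whose id or name
#' contains `extracellular` (or whose id starts with `e`) map to the
#' extracellular compartment; everything else to the cytosol. Reaction types
#' are re-inferred (exchange = single extracellular species, biomass = the
#' objective). Bounds absent everywhere default to -1000/1000 for
#' `reversible="true"` reactions and 0/1000 otherwise.
#'
#' @param path SBML file path.
#' @return A `metabolic_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) abort(sprintf("SBML parse error in '%s': %s",
                                      path, conditionMessage(e)))
  )
  find1 <- function(node, nm) {
    xml2::xml_find_first(node, sprintf(".//*[local-name()='%s']", nm))
  }
  findall <- function(node, nm) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", nm))
  }
  model_node <- find1(doc, "model")
  if (inherits(model_node, "xml_missing")) abort("SBML file has no <model>.")

  # compartments
  comp_nodes <- findall(model_node, "compartment")
  comp_map <- setNames(
    vapply(comp_nodes, function(cn) {
      cid <- xml2::xml_attr(cn, "id")
      cname <- xml2::xml_attr(cn, "name")
      hay <- tolower(paste(cid, cname))
      if (grepl("extracellular", hay) || grepl("^e[0-9]*$", tolower(cid))) {
        "extracellular"
      } else {
        "cytosol"
      }
    }, character(1)),
    vapply(comp_nodes, xml2::xml_attr, character(1), attr = "id")
  )

  # species
  sp_nodes <- xml2::xml_find_all(
    model_node, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- tibble(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"),
                           xml2::xml_attr(sp_nodes, "id")),
    formula = dplyr::coalesce(xml2::xml_attr(sp_nodes, "chemicalFormula"), ""),
    charge = suppressWarnings(as.integer(xml2::xml_attr(sp_nodes, "charge"))),
    compartment = unname(comp_map[xml2::xml_attr(sp_nodes, "compartment")]),
    boundary = dplyr::coalesce(
      xml2::xml_attr(sp_nodes, "boundaryCondition") == "true", FALSE)
  )

  # global flux-bound parameters (fbc dialect)
  par_nodes <- xml2::xml_find_all(
    model_node,
    ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_map <- setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                      xml2::xml_attr(par_nodes, "id"))

  # gene products (fbc)
  gp_nodes <- findall(model_node, "geneProduct")
  gp_map <- setNames(
    dplyr::coalesce(xml2::xml_attr(gp_nodes, "label"),
                    xml2::xml_attr(gp_nodes, "id")),
    xml2::xml_attr(gp_nodes, "id")
  )

  rxn_nodes <- xml2::xml_find_all(
    model_node,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rxn_nodes) == 0L) abort("SBML model declares no reactions.")

  parse_refs <- function(rn, listname, sign) {
    refs <- xml2::xml_find_all(rn, sprintf(
      "./*[local-name()='%s']/*[local-name()='speciesReference']", listname))
    if (length(refs) == 0L) return(setNames(numeric(0), character(0)))
    coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    coef[is.na(coef)] <- 1
    setNames(sign * coef, xml2::xml_attr(refs, "species"))
  }
  rows <- map(rxn_nodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    st_sub <- parse_refs(rn, "listOfReactants", -1)
    st_pro <- parse_refs(rn, "listOfProducts", 1)
    st <- c(st_sub, st_pro)
    if (anyDuplicated(names(st))) { # species on both sides: net coefficient
      agg <- tapply(st, names(st), sum)
      st <- setNames(as.numeric(agg), names(agg))
      st <- st[abs(st) > 0]
    }
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lb <- ub <- NA_real_
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    if (!is.na(lb_ref) && lb_ref %in% names(par_map)) lb <- par_map[[lb_ref]]
    if (!is.na(ub_ref) && ub_ref %in% names(par_map)) ub <- par_map[[ub_ref]]
    if (is.na(lb) || is.na(ub)) {
      # legacy: kinetic-law local parameters
      kl_pars <- xml2::xml_find_all(rn, paste0(
        "./*[local-name()='kineticLaw']//*[local-name()='parameter' or ",
        "local-name()='localParameter']"))
      if (length(kl_pars) > 0L) {
        kl_ids <- xml2::xml_attr(kl_pars, "id")
        kl_val <- as.numeric(xml2::xml_attr(kl_pars, "value"))
        if (is.na(lb) && "LOWER_BOUND" %in% kl_ids) {
          lb <- kl_val[match("LOWER_BOUND", kl_ids)]
        }
        if (is.na(ub) && "UPPER_BOUND" %in% kl_ids) {
          ub <- kl_val[match("UPPER_BOUND", kl_ids)]
        }
      }
    }
    if (is.na(lb)) lb <- if (rev) -1000 else 0
    if (is.na(ub)) ub <- 1000
    gpr <- read_gpr(rn, gp_map)
    tibble(id = id,
           name = dplyr::coalesce(xml2::xml_attr(rn, "name"), id),
           stoichiometry = list(st), lower_bound = lb, upper_bound = ub,
           gpr = gpr, rtype = NA_character_)
  })
  rxns <- bind_rows(rows)

  flipped <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  if (length(flipped) > 0L) {
    abort(sprintf("Reversed bounds (lb > ub) for reaction(s): %s.",
                  paste(flipped, collapse = ", ")))
  }

  # objective: fbc active objective, else the legacy single-biomass fallback
  objective_id <- NA_character_
  obj_list <- find1(model_node, "listOfObjectives")
  if (!inherits(obj_list, "xml_missing")) {
    active <- xml2::xml_attr(obj_list, "activeObjective")
    objs <- findall(obj_list, "objective")
    obj <- if (!is.na(active)) {
      objs[xml2::xml_attr(objs, "id") == active]
    } else {
      objs
    }
    if (length(obj) > 0L) {
      fo <- findall(obj[[1]], "fluxObjective")
      if (length(fo) > 0L) objective_id <- xml2::xml_attr(fo[[1]], "reaction")
    }
  }
  if (is.na(objective_id)) {
    hits <- grepl("biomass", rxns$id, ignore.case = TRUE) |
      grepl("biomass", rxns$name, ignore.case = TRUE)
    if (sum(hits) != 1L) {
      abort(sprintf(
        "No objective: SBML declares none and %d reaction(s) match 'biomass'.",
        sum(hits)))
    }
    objective_id <- rxns$id[hits]
  }
  metabolic_model(mets, rxns, objective_id = objective_id)
}

# Reconstruct a boolean GPR string from an fbc geneProductAssociation, or
# fall back to a legacy GENE_ASSOCIATION note.
read_gpr <- function(rn, gp_map) {
  gpa <- xml2::xml_find_first(
    rn, "./*[local-name()='geneProductAssociation']")
  if (!inherits(gpa, "xml_missing")) {
    kids <- xml2::xml_children(gpa)
    if (length(kids) > 0L) return(gpr_node_to_string(kids[[1]], gp_map, top = TRUE))
  }
  notes <- xml2::xml_find_first(rn, "./*[local-name()='notes']")
  if (!inherits(notes, "xml_missing")) {
    txt <- xml2::xml_text(notes)
    m <- regmatches(txt, regexpr("GENE_ASSOCIATION:[^\n]*", txt))
    if (length(m) == 1L) return(trimws(sub("GENE_ASSOCIATION:", "", m)))
  }
  ""
}

gpr_node_to_string <- function(node, gp_map, top = FALSE) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    return(gp_map[ref] %|na|% ref)
  }
  op <- if (nm == "and") " and " else " or "
  parts <- vapply(xml2::xml_children(node), gpr_node_to_string,
                  character(1), gp_map = gp_map)
  inner <- paste(parts, collapse = op)
  if (top) inner else paste0("(", inner, ")")
}

`%|na|%` <- function(x, y) if (is.na(x)) y else unname(x)

#' Write a metabolic model as SBML Level 3 + fbc
#'
#' Emits Level 3 Version 1 with fbc version 2: species carry
#' `fbc:chemicalFormula`/`fbc:charge` and `boundaryCondition`, flux bounds go
#' through deduplicated global parameters, the objective through
#' `fbc:listOfObjectives`, and gene associations through
#' `fbc:geneProductAssociation` over a `fbc:listOfGeneProducts`. The file
#' re-reads to an equivalent model.
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @param model_id Id written on the `<model>` element.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path, model_id = "model") {
  validate_model(model)
  root <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
    level = "3", version = "1", "fbc:required" = "false"
  )
  mn <- xml2::xml_add_child(root, "model", id = model_id,
                            "fbc:strict" = "true")

  lc <- xml2::xml_add_child(mn, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "c", name = "cytosol",
                      constant = "true")
  xml2::xml_add_child(lc, "compartment", id = "e", name = "extracellular",
                      constant = "true")

  ls <- xml2::xml_add_child(mn, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    attrs <- list(
      id = m$id, name = m$name,
      compartment = if (m$compartment == "extracellular") "e" else "c",
      hasOnlySubstanceUnits = "false",
      boundaryCondition = if (m$boundary) "true" else "false",
      constant = "false"
    )
    if (nzchar(m$formula)) attrs[["fbc:chemicalFormula"]] <- m$formula
    if (!is.na(m$charge)) attrs[["fbc:charge"]] <- as.character(m$charge)
    do.call(xml2::xml_add_child, c(list(ls, "species"), attrs))
  }

  # deduplicated bound parameters
  vals <- sort(unique(c(model$reactions$lower_bound,
                        model$reactions$upper_bound)))
  par_ids <- setNames(sprintf("fb_%d", seq_along(vals)),
                      format_num(vals))
  lp <- xml2::xml_add_child(mn, "listOfParameters")
  for (v in vals) {
    xml2::xml_add_child(lp, "parameter", id = par_ids[[format_num(v)]],
                        value = format_num(v), constant = "true",
                        sboTerm = "SBO:0000626")
  }

  genes <- model_genes(model)
  gene_ids <- setNames(sprintf("G_%s", gsub("[^A-Za-z0-9_]", "_", genes)),
                       genes)

  lr <- xml2::xml_add_child(mn, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    st <- r$stoichiometry[[1]]
    rn <- xml2::xml_add_child(
      lr, "reaction", id = r$id, name = r$name,
      reversible = if (r$lower_bound < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = par_ids[[format_num(r$lower_bound)]],
      "fbc:upperFluxBound" = par_ids[[format_num(r$upper_bound)]]
    )
    if (nzchar(r$gpr)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      write_gpr_node(gpa, parse_gpr(r$gpr), gene_ids)
    }
    subs <- st[st < 0]
    pros <- st[st > 0]
    if (length(subs) > 0L) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (k in seq_along(subs)) {
        xml2::xml_add_child(lre, "speciesReference", species = names(subs)[k],
                            stoichiometry = format_num(-subs[[k]]),
                            constant = "true")
      }
    }
    if (length(pros) > 0L) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (k in seq_along(pros)) {
        xml2::xml_add_child(lpr, "speciesReference", species = names(pros)[k],
                            stoichiometry = format_num(pros[[k]]),
                            constant = "true")
      }
    }
  }

  lo <- xml2::xml_add_child(mn, "fbc:listOfObjectives",
                            "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(lf, "fbc:fluxObjective",
                      "fbc:reaction" = model$objective_id,
                      "fbc:coefficient" = "1")

  if (length(genes) > 0L) {
    lg <- xml2::xml_add_child(mn, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct", "fbc:id" = gene_ids[[g]],
                          "fbc:label" = g)
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}

format_num <- function(x) sprintf("%.10g", x)

# --- tiny recursive-descent parser for boolean GPR strings ----------------
# expr := term ('or' term)* ; term := factor ('and' factor)* ;
# factor := identifier | '(' expr ')'
parse_gpr <- function(s) {
  toks <- gpr_tokens(s)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  node <- gpr_expr(st)
  if (st$pos <= length(st$toks)) {
    abort(sprintf("Trailing tokens in gene association '%s'.", s))
  }
  node
}

gpr_tokens <- function(s) {
  s <- gsub("([()])", " \\1 ", s)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA

gpr_expr <- function(st) {
  parts <- list(gpr_term(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    parts[[length(parts) + 1L]] <- gpr_term(st)
  }
  if (length(parts) == 1L) parts[[1]] else list(op = "or", args = parts)
}

gpr_term <- function(st) {
  parts <- list(gpr_factor(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    parts[[length(parts) + 1L]] <- gpr_factor(st)
  }
  if (length(parts) == 1L) parts[[1]] else list(op = "and", args = parts)
}

gpr_factor <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) abort("Unexpected end of gene association.")
  st$pos <- st$pos + 1L
  if (tok == "(") {
    node <- gpr_expr(st)
    if (!identical(gpr_peek(st), ")")) {
      abort("Unbalanced parentheses in gene association.")
    }
    st$pos <- st$pos + 1L
    return(node)
  }
  if (tok %in% c(")", "and", "or")) {
    abort(sprintf("Unexpected token '%s' in gene association.", tok))
  }
  tok
}

write_gpr_node <- function(parent, node, gene_ids) {
  if (is.character(node)) {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = gene_ids[[node]])
    return(invisible(NULL))
  }
  el <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
  for (a in node$args) write_gpr_node(el, a, gene_ids)
  invisible(NULL)
}
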