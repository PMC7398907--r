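#' The hydrolytic atrazine degradation pathway
#'
#' Builds the three-step hydrolytic route of *P. aurescens* TC1 — triazine
#' hydrolase (TrzN), hydroxyatrazine hydrolase (AtzB) and
#' N-isopropylammelide isopropylamino hydrolase (AtzC) — plus lumped
#' catabolism of the released alkylamines, as a fully balanced, injectable
#' reaction set:
#'
#' * `TrzN`: atrazine + H2O -> hydroxyatrazine + Cl- + H+
#' * `AtzB`: hydroxyatrazine + H2O -> N-isopropylammelide + ethylamine
#' * `AtzC`: N-isopropylammelide + H2O -> cyanuric acid + isopropylamine
#' * `ETHAM_DEG`: ethylamine + H2O + H+ -> acetaldehyde + NH4+ + H2
#' * `IPAM_DEG`: isopropylamine + 2 H2O -> L-alanine + 3 H2
#'
#' The triazine ring is not cleaved in TC1: cyanuric acid is exported and
#' accumulates stoichiometrically, one mole per mole of atrazine consumed.
#' Unlike the ring, the two side chains are catabolizable, so of atrazine's
#' 8 C and 5 N atoms, 5 C and 2 N are bioavailable. Deaminated nitrogen is
#' released as ammonium; chloride leaves as dissociated Cl- + H+. The lumped
#' amine reactions are written cofactor-neutral, with reducing equivalents
#' leaving as H2 through a dedicated exchange.
#'
#' @return An object of class `pathway_spec`: list with `reactions` (reaction
#'   tibble in [metabolic_model()] layout), `metabolites` (declarations for
#'   every species the pathway touches, including host-side ones such as
#'   water, protons, ammonium, acetaldehyde and L-alanine), and `species`
#'   (named formula vector of the pathway intermediates).
#' @examples
#' spec <- build_atrazine_pathway()
#' spec$species[["atrazine"]]
#' @export
build_atrazine_pathway <- function() {
  species <- c(
    atrazine = "C8H14ClN5",
    hydroxyatrazine = "C8H15N5O",
    n_isopropylammelide = "C6H10N4O2",
    cyanuric_acid = "C3H3N3O3",
    ethylamine = "C2H7N",
    isopropylamine = "C3H9N",
    acetaldehyde = "C2H4O",
    l_alanine = "C3H7NO2"
  )
  mets <- tibble(
    id = c("atz_e", "atz_c", "hxatz_c", "ipmd_c", "cya_c", "cya_e",
           "cl_c", "cl_e", "etham_c", "ipam_c",
           "h2o_c", "h_c", "h2_c", "nh4_c", "acald_c", "ala_c"),
    name = c("atrazine", "atrazine", "hydroxyatrazine",
             "N-isopropylammelide", "cyanuric acid", "cyanuric acid",
             "chloride", "chloride", "ethylamine", "isopropylamine",
             "water", "proton", "hydrogen", "ammonium", "acetaldehyde",
             "L-alanine"),
    formula = c("C8H14ClN5", "C8H14ClN5", "C8H15N5O", "C6H10N4O2",
                "C3H3N3O3", "C3H3N3O3", "Cl", "Cl", "C2H7N", "C3H9N",
                "H2O", "H", "H2", "H4N", "C2H4O", "C3H7NO2"),
    charge = c(0L, 0L, 0L, 0L, 0L, 0L, -1L, -1L, 0L, 0L,
               0L, 1L, 0L, 1L, 0L, 0L),
    compartment = c("extracellular", "cytosol", "cytosol", "cytosol",
                    "cytosol", "extracellular", "cytosol", "extracellular",
                    "cytosol", "cytosol", "cytosol", "cytosol", "cytosol",
                    "cytosol", "cytosol", "cytosol"),
    boundary = FALSE
  )
  st <- function(...) list(c(...))
  rxns <- tibble(
    id = c("EX_atz", "T_atz", "TrzN", "AtzB", "AtzC",
           "ETHAM_DEG", "IPAM_DEG", "T_cya", "EX_cya", "T_cl", "EX_cl"),
    name = c("atrazine exchange", "atrazine transport",
             "triazine hydrolase",
             "hydroxyatrazine hydrolase",
             "N-isopropylammelide isopropylamino hydrolase",
             "ethylamine catabolism (lumped)",
             "isopropylamine catabolism to L-alanine (lumped)",
             "cyanuric acid export", "cyanuric acid exchange",
             "chloride export", "chloride exchange"),
    stoichiometry = c(
      st(atz_e = -1),
      st(atz_e = -1, atz_c = 1),
      st(atz_c = -1, h2o_c = -1, hxatz_c = 1, cl_c = 1, h_c = 1),
      st(hxatz_c = -1, h2o_c = -1, ipmd_c = 1, etham_c = 1),
      st(ipmd_c = -1, h2o_c = -1, cya_c = 1, ipam_c = 1),
      st(etham_c = -1, h2o_c = -1, h_c = -1, acald_c = 1, nh4_c = 1, h2_c = 1),
      st(ipam_c = -1, h2o_c = -2, ala_c = 1, h2_c = 3),
      st(cya_c = -1, cya_e = 1),
      st(cya_e = -1),
      st(cl_c = -1, cl_e = 1),
      st(cl_e = -1)
    ),
    lower_bound = 0,
    upper_bound = 1000,
    gpr = c("", "", "trzN", "atzB", "atzC", "", "", "", "", "", ""),
    rtype = c("exchange", "transport", "cytosolic", "cytosolic", "cytosolic",
              "cytosolic", "cytosolic", "transport", "exchange",
              "transport", "exchange")
  )
  structure(list(reactions = rxns, metabolites = mets, species = species),
            class = "pathway_spec")
}

#' Inject the atrazine pathway into a host model
#'
#' Adds the pathway reactions and any pathway metabolites the host does not
#' already declare. The augmented model still passes the balance audit.
#' Whether atrazine can then serve as a sole carbon and nitrogen source
#' depends on the host: it must catabolize acetaldehyde, L-alanine and
#' ammonium (as TOY-2 does); a host without amine catabolism gains no growth
#' from atrazine.
#'
#' @param model Host `metabolic_model`.
#' @param spec A `pathway_spec` from [build_atrazine_pathway()].
#' @param overwrite Allow replacing reactions whose ids collide with the
#'   pathway's; default errors on collision.
#' @return The augmented `metabolic_model`.
#' @examples
#' toy <- inject_pathway(make_toy_model("TOY-2"), build_atrazine_pathway())
#' @export
inject_pathway <- function(model, spec = build_atrazine_pathway(),
                           overwrite = FALSE) {
  clash <- intersect(spec$reactions$id, model$reactions$id)
  if (length(clash) > 0L && !overwrite) {
    abort(sprintf("Pathway reaction id(s) already in model: %s.",
                  paste(clash, collapse = ", ")))
  }
  new_mets <- spec$metabolites[!spec$metabolites$id %in% model$metabolites$id, ]
  rxns <- model$reactions[!model$reactions$id %in% spec$reactions$id, ]
  metabolic_model(
    metabolites = bind_rows(model$metabolites, new_mets),
    reactions = bind_rows(rxns, spec$reactions),
    objective_id = model$objective_id
  )
}

#' Bioavailable carbon and nitrogen per mole of atrazine
#'
#' Atoms routed to catabolizable products (everything except the exported
#' cyanuric acid ring): with the canonical pathway, 5 of 8 carbons and 2 of
#' 5 nitrogens.
#'
#' @param spec A `pathway_spec`.
#' @param ring_catabolized Hypothetical switch: count the cyanuric acid ring
#'   as bioavailable too.
#' @return A one-row tibble with `carbon` and `nitrogen`.
#' @examples
#' bioavailable_cn()  # 5 C, 2 N
#' @export
bioavailable_cn <- function(spec = build_atrazine_pathway(),
                            ring_catabolized = FALSE) {
  if (length(spec$species) == 0L) return(tibble(carbon = 0, nitrogen = 0))
  total <- cn_ratio(spec$species[["atrazine"]])
  ring <- cn_ratio(spec$species[["cyanuric_acid"]])
  if (ring_catabolized) return(total)
  tibble(carbon = total$carbon - ring$carbon,
         nitrogen = total$nitrogen - ring$nitrogen)
}

#' Serialize a pathway spec as a reaction TSV
#'
#' @param spec A `pathway_spec`.
#' @param path Output file.
#' @export
write_pathway_tsv <- function(spec, path) {
  tbl <- mutate(spec$reactions,
                stoichiometry = map_chr(.data$stoichiometry, format_stoich))
  readr::write_tsv(tbl, path)
  invisible(path)
}
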