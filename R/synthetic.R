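#' Analytic toy models
#'
#' Desk-scale fixtures with closed-form FBA optima, used to test every stage
#' of the pipeline without a genome-scale reconstruction.
#'
#' **TOY-1** — glucose/ammonium bottleneck network: exchanges `EX_glc`,
#' `EX_nh4`, transports `T_glc`, `T_nh4` (ammonium transport reversible, so
#' surplus nitrogen can be secreted) and `BIOMASS: 1 glc_c + 0.5 nh4_c ->
#' biomass`. Five metabolites (the biomass product is a boundary species) and
#' five reactions. With uptake bounds `(g, a)` the optimum is
#' `mu = min(g, a / 0.5)`.
#'
#' **TOY-2** — TOY-1 plus the catabolic context the atrazine pathway needs:
#' acetaldehyde assimilation (`3 acald + 3 H2O -> glc + 3 H2`), L-alanine
#' deamination (`ala + H2O + H+ -> pyruvate + NH4+ + H2`), gluconeogenesis
#' (`2 pyr + 2 H2 -> glc`), water/proton/hydrogen exchanges, and phosphate
#' (`0.1 pi_c` per unit biomass flux) so phosphate limitation is
#' representable. On glucose + ammonium + phosphate `(g, a, p)` the optimum
#' is `mu = min(g, a / 0.5, p / 0.1)`. With the pathway injected and atrazine
#' as sole C/N source at uptake `u`, carbon limits growth at
#' `mu = (5/6) u` (5 bioavailable C per atrazine, 6 C per glucose
#' equivalent).
#'
#' @param name `"TOY-1"` or `"TOY-2"`.
#' @return A `metabolic_model`.
#' @examples
#' solve_fba(make_toy_model("TOY-1"), c(EX_glc = 10, EX_nh4 = 10))
#' @export
make_toy_model <- function(name = c("TOY-1", "TOY-2")) {
  name <- match.arg(name)
  st <- function(...) list(c(...))
  mets1 <- tibble(
    id = c("glc_e", "glc_c", "nh4_e", "nh4_c", "biomass"),
    name = c("D-glucose", "D-glucose", "ammonium", "ammonium", "biomass"),
    formula = c("C6H12O6", "C6H12O6", "H4N", "H4N", ""),
    charge = c(0L, 0L, 1L, 1L, NA_integer_),
    compartment = c("extracellular", "cytosol", "extracellular", "cytosol",
                    "cytosol"),
    boundary = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  rxns1 <- tibble(
    id = c("EX_glc", "EX_nh4", "T_glc", "T_nh4", "BIOMASS"),
    name = c("glucose exchange", "ammonium exchange", "glucose transport",
             "ammonium transport", "biomass"),
    stoichiometry = c(
      st(glc_e = -1), st(nh4_e = -1),
      st(glc_e = -1, glc_c = 1), st(nh4_e = -1, nh4_c = 1),
      st(glc_c = -1, nh4_c = -0.5, biomass = 1)
    ),
    lower_bound = c(0, 0, 0, -1000, 0),
    upper_bound = 1000,
    gpr = "",
    rtype = c("exchange", "exchange", "transport", "transport", "biomass")
  )
  if (name == "TOY-1") {
    return(metabolic_model(mets1, rxns1, objective_id = "BIOMASS"))
  }
  mets2 <- bind_rows(mets1, tibble(
    id = c("pi_e", "pi_c", "acald_c", "ala_c", "pyr_c",
           "h2o_e", "h2o_c", "h_e", "h_c", "h2_e", "h2_c"),
    name = c("phosphate", "phosphate", "acetaldehyde", "L-alanine",
             "pyruvate", "water", "water", "proton", "proton",
             "hydrogen", "hydrogen"),
    formula = c("HO4P", "HO4P", "C2H4O", "C3H7NO2", "C3H4O3",
                "H2O", "H2O", "H", "H", "H2", "H2"),
    charge = c(-2L, -2L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 0L, 0L),
    compartment = c("extracellular", "cytosol", "cytosol", "cytosol",
                    "cytosol", "extracellular", "cytosol", "extracellular",
                    "cytosol", "extracellular", "cytosol"),
    boundary = FALSE
  ))
  rxns2 <- rxns1
  rxns2$stoichiometry[[5]] <- c(glc_c = -1, nh4_c = -0.5, pi_c = -0.1,
                                biomass = 1)
  rxns2 <- bind_rows(rxns2, tibble(
    id = c("EX_pi", "EX_h2o", "EX_h", "EX_h2",
           "T_pi", "T_h2o", "T_h", "T_h2",
           "ACALD_ASSIM", "ALA_DEG", "PYR_GLC"),
    name = c("phosphate exchange", "water exchange", "proton exchange",
             "hydrogen exchange", "phosphate transport", "water transport",
             "proton transport", "hydrogen export",
             "acetaldehyde assimilation", "L-alanine deamination",
             "gluconeogenesis from pyruvate"),
    stoichiometry = c(
      st(pi_e = -1), st(h2o_e = -1), st(h_e = -1), st(h2_e = -1),
      st(pi_e = -1, pi_c = 1), st(h2o_e = -1, h2o_c = 1),
      st(h_e = -1, h_c = 1), st(h2_c = -1, h2_e = 1),
      st(acald_c = -3, h2o_c = -3, glc_c = 1, h2_c = 3),
      st(ala_c = -1, h2o_c = -1, h_c = -1, pyr_c = 1, nh4_c = 1, h2_c = 1),
      st(pyr_c = -2, h2_c = -2, glc_c = 1)
    ),
    lower_bound = c(0, 0, 0, 0, 0, -1000, -1000, 0, 0, 0, 0),
    upper_bound = 1000,
    gpr = "",
    rtype = c("exchange", "exchange", "exchange", "exchange",
              "transport", "transport", "transport", "transport",
              "cytosolic", "cytosolic", "cytosolic")
  ))
  metabolic_model(mets2, rxns2, objective_id = "BIOMASS")
}

#' The minimal mineral medium (MMM)
#'
#' The ion/gas-only base medium: K+, Mn2+, CO2, Zn2+, SO4(2-), Cu2+, Ca2+,
#' HPO4(2-), Mg2+, Fe2+ and Cl- — exactly eleven exchange entries at a
#' generous default bound, with optional supplements merged on top
#' (a supplement overriding an MMM entry keeps the supplement's bound).
#' Exchange ids follow the `EX_<ion>` convention used by the fixtures.
#'
#' @param supplements Optional named numeric vector or `pa_media` of
#'   additional uptake bounds (e.g. `c(EX_atz = 1, EX_glc = 10)`).
#' @param ion_bound Default uptake bound for the mineral ions.
#' @return A `pa_media`.
#' @examples
#' nrow(make_mmm_media())                       # 11
#' nrow(make_mmm_media(c(EX_atz = 1, EX_glc = 10)))  # 13
#' @export
make_mmm_media <- function(supplements = NULL, ion_bound = 1000) {
  ions <- c("EX_k", "EX_mn2", "EX_co2", "EX_zn2", "EX_so4", "EX_cu2",
            "EX_ca2", "EX_pi", "EX_mg2", "EX_fe2", "EX_cl")
  base <- media(setNames(rep(ion_bound, length(ions)), ions), name = "MMM")
  if (is.null(supplements)) return(base)
  media_with(base, supplements)
}

#' Random mass-balanced linear-pathway models
#'
#' Generates a deterministic (seeded) model built from one linear pathway
#' over synthetic species with formulas `E<k>` in a single pseudo-element, so
#' elemental balance is provable by construction: each chain reaction
#' `a X_i -> b X_(i+1)` satisfies `a k_i = b k_(i+1)`. The chain starts at an
#' exchange + transport pair and ends in a biomass drain to a boundary
#' species. All reactions are irreversible and the network is loop-free, so
#' closing the exchange provably yields zero growth.
#'
#' @param seed Integer seed (generator is deterministic given the seed).
#' @param n_reactions Total reaction count, `>= 3` (exchange, transport and
#'   biomass included).
#' @return A `metabolic_model`.
#' @examples
#' m <- make_random_balanced_model(42, 8)
#' audit_model_balance(m)$passed
#' @export
make_random_balanced_model <- function(seed, n_reactions = 8L) {
  if (n_reactions < 3L) abort("`n_reactions` must be >= 3.")
  set.seed(seed)
  n_chain <- n_reactions - 3L
  n_species <- n_chain + 1L
  k <- sample(1:4, n_species, replace = TRUE)
  ids <- sprintf("S%d_c", seq_len(n_species))
  mets <- tibble(
    id = c("S1_e", ids, "biomass"),
    name = c("S1", sprintf("S%d", seq_len(n_species)), "biomass"),
    formula = c(sprintf("E%d", k[1]), sprintf("E%d", k), ""),
    charge = 0L,
    compartment = c("extracellular", rep("cytosol", n_species), "cytosol"),
    boundary = c(rep(FALSE, n_species + 1L), TRUE)
  )
  mets$charge[mets$id == "biomass"] <- NA_integer_
  rxns <- list(
    tibble(id = "EX_S1", name = "S1 exchange",
           stoichiometry = list(c(S1_e = -1)),
           lower_bound = 0, upper_bound = 1000, gpr = "", rtype = "exchange"),
    tibble(id = "T_S1", name = "S1 transport",
           stoichiometry = list(c(S1_e = -1, S1_c = 1)),
           lower_bound = 0, upper_bound = 1000, gpr = "", rtype = "transport")
  )
  for (i in seq_len(n_chain)) {
    g <- gcd(k[i], k[i + 1L])
    a <- k[i + 1L] / g
    b <- k[i] / g
    rxns[[length(rxns) + 1L]] <- tibble(
      id = sprintf("R%d", i), name = sprintf("S%d -> S%d", i, i + 1L),
      stoichiometry = list(setNames(c(-a, b), c(ids[i], ids[i + 1L]))),
      lower_bound = 0, upper_bound = 1000,
      gpr = sprintf("gene%d", i), rtype = "cytosolic"
    )
  }
  bio_coef <- sample(1:3, 1)
  rxns[[length(rxns) + 1L]] <- tibble(
    id = "BIOMASS", name = "biomass",
    stoichiometry = list(setNames(c(-bio_coef, 1),
                                  c(ids[n_species], "biomass"))),
    lower_bound = 0, upper_bound = 1000, gpr = "", rtype = "biomass"
  )
  metabolic_model(mets, bind_rows(rxns), objective_id = "BIOMASS")
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
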