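# Shared fixture builders (everything generated in code; no files needed).

toy1_media <- function(glc = 10, nh4 = 10) {
  media(c(EX_glc = glc, EX_nh4 = nh4), name = "toy-glc-nh4")
}

# media for the pathway-injected TOY-2: atrazine as sole C/N source, with
# water/protons and phosphate non-limiting unless overridden
atrazine_media <- function(atz = 1, pi = 10, extra = NULL) {
  m <- media(c(EX_atz = atz, EX_h2o = 1000, EX_h = 1000, EX_pi = pi))
  if (is.null(extra)) m else media_with(m, extra)
}

pathway_toy <- function() {
  inject_pathway(make_toy_model("TOY-2"), build_atrazine_pathway())
}

# TOY-1 plus mass-from-nothing generators for both biomass precursors:
# a deliberately broken network for the energy-loop audit
free_lunch_toy <- function() {
  t1 <- make_toy_model("TOY-1")
  extra <- tibble::tibble(
    id = c("FREE_C", "FREE_N"),
    name = c("spurious glucose generator", "spurious ammonium generator"),
    stoichiometry = list(c(glc_c = 1), c(nh4_c = 1)),
    lower_bound = 0, upper_bound = 1000, gpr = "",
    rtype = "cytosolic"
  )
  metabolic_model(t1$metabolites, dplyr::bind_rows(t1$reactions, extra),
                  "BIOMASS")
}

expect_tbl_equal <- function(a, b, tol = 1e-9) {
  testthat::expect_equal(as.data.frame(a), as.data.frame(b),
                         tolerance = tol, ignore_attr = TRUE)
}

# model equality up to row order of tables and element order of stoichiometry
expect_model_equal <- function(a, b) {
  norm_mets <- function(m) dplyr::arrange(m$metabolites, id)
  norm_rxns <- function(m) {
    r <- dplyr::arrange(m$reactions, id)
    r$stoichiometry <- lapply(r$stoichiometry, function(s) s[order(names(s))])
    r
  }
  testthat::expect_equal(norm_mets(a), norm_mets(b), ignore_attr = TRUE)
  testthat::expect_equal(norm_rxns(a), norm_rxns(b), ignore_attr = TRUE)
  testthat::expect_identical(a$objective_id, b$objective_id)
}
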