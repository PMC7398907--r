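test_that("FBA reproduces the analytic bottleneck optima of TOY-1", {
  t1 <- make_toy_model("TOY-1")
  # biomass draws 1 glucose + 0.5 ammonium: mu = min(g, a / 0.5)
  expect_equal(solve_fba(t1, toy1_media(10, 10))$objective_value, 10,
               tolerance = 1e-9)
  expect_equal(solve_fba(t1, toy1_media(10, 2))$objective_value, 4,
               tolerance = 1e-9)
  expect_equal(solve_fba(t1, media())$objective_value, 0)
})

test_that("FBA solutions satisfy steady state and bounds at optimum", {
  models <- list(
    list(make_toy_model("TOY-1"), toy1_media()),
    list(pathway_toy(), atrazine_media(extra = c(EX_glc = 3))),
    list(make_random_balanced_model(3, 7), media(c(EX_S1 = 5)))
  )
  for (mm in models) {
    model <- apply_media(mm[[1]], mm[[2]])
    sol <- solve_fba(model)
    expect_equal(sol$status, "optimal")
    v <- sol$fluxes[model$reactions$id]
    S <- build_stoichiometric_matrix(model)
    S <- S[!model$metabolites$boundary, , drop = FALSE]
    expect_lt(max(abs(as.numeric(S %*% v))), 1e-6)
    expect_true(all(v >= model$reactions$lower_bound - 1e-6))
    expect_true(all(v <= model$reactions$upper_bound + 1e-6))
  }
})

test_that("FBA objective matches the brute-force vertex oracle on small nets", {
  # all fixtures here have <= 8 reactions; the oracle enumerates vertices
  cases <- list(
    list(make_toy_model("TOY-1"), toy1_media(10, 10)),
    list(make_toy_model("TOY-1"), toy1_media(10, 2)),
    list(make_toy_model("TOY-1"), toy1_media(0, 10)),
    list(make_toy_model("TOY-1"), media(c(EX_glc = 7.3))),
    list(free_lunch_toy(), media())
  )
  for (seed in c(2, 5, 9, 14, 23)) {
    cases[[length(cases) + 1]] <-
      list(make_random_balanced_model(seed, sample(3:8, 1)),
           media(c(EX_S1 = runif(1, 0, 20))))
  }
  for (cs in cases) {
    got <- solve_fba(cs[[1]], cs[[2]])$objective_value
    want <- oracle_fba_max(cs[[1]], cs[[2]])
    expect_true(want$feasible)
    expect_equal(got, want$value, tolerance = 1e-6)
  }
})

test_that("optimum scales with media and is monotone in uptake bounds", {
  t1 <- make_toy_model("TOY-1")
  base <- solve_fba(t1, toy1_media(4, 3))$objective_value
  for (k in c(0, 0.5, 2, 7)) {
    expect_equal(solve_fba(t1, toy1_media(4 * k, 3 * k))$objective_value,
                 k * base, tolerance = 1e-9)
  }
  # enlarging any single uptake never decreases the optimum
  set.seed(42)
  for (rep in 1:10) {
    g <- runif(1, 0, 20); a <- runif(1, 0, 20)
    mu <- solve_fba(t1, toy1_media(g, a))$objective_value
    expect_gte(solve_fba(t1, toy1_media(g + runif(1, 0, 10), a)
                         )$objective_value, mu - 1e-9)
    expect_gte(solve_fba(t1, toy1_media(g, a + runif(1, 0, 10))
                         )$objective_value, mu - 1e-9)
  }
})

test_that("FVA brackets the FBA flux and pins forced reactions", {
  t1 <- make_toy_model("TOY-1")
  med <- toy1_media(10, 10)
  fva <- run_fva(t1, med)
  sol <- solve_fba(t1, med)
  for (i in seq_len(nrow(fva))) {
    v <- sol$fluxes[[fva$reaction[i]]]
    expect_lte(fva$min[i], v + 1e-6)
    expect_gte(fva$max[i], v - 1e-6)
    expect_lte(fva$min[i], fva$max[i] + 1e-12)
  }
  # single-pathway network: glucose uptake fully determined at optimum
  glc <- fva[fva$reaction == "EX_glc", ]
  expect_equal(glc$min, -10, tolerance = 1e-6)
  expect_equal(glc$max, -10, tolerance = 1e-6)
})

test_that("FVA exposes degenerate optima over duplicate transporters", {
  t1 <- make_toy_model("TOY-1")
  r <- dplyr::bind_rows(t1$reactions, tibble::tibble(
    id = "T_glc2", name = "duplicate glucose transporter",
    stoichiometry = list(c(glc_e = -1, glc_c = 1)),
    lower_bound = 0, upper_bound = 1000, gpr = "", rtype = "transport"))
  dup <- metabolic_model(t1$metabolites, r, "BIOMASS")
  fva <- run_fva(dup, toy1_media(10, 10), reaction_ids = c("T_glc", "T_glc2"))
  # each transporter alone can carry anything from nothing to all 10 units
  expect_equal(fva$min, c(0, 0), tolerance = 1e-6)
  expect_equal(fva$max, c(10, 10), tolerance = 1e-6)
})

test_that("FVA at fraction 0 reduces to plain bounds propagation", {
  t1 <- make_toy_model("TOY-1")
  fva <- run_fva(t1, toy1_media(10, 10), reaction_ids = "BIOMASS",
                 objective_fraction = 0)
  expect_equal(fva$min, 0, tolerance = 1e-9)   # biomass can idle
  expect_equal(fva$max, 10, tolerance = 1e-6)  # or run at the optimum
  expect_error(run_fva(t1, toy1_media(), objective_fraction = 1.2), "0, 1")
})

test_that("degradation capacity reports forced uptake at the optimum", {
  toy <- pathway_toy()
  med <- atrazine_media(atz = 1)
  cap <- degradation_capacity(toy, med, "EX_atz")
  # atrazine is the sole C source: its uptake is stoichiometrically forced
  expect_equal(cap$min_uptake, 1, tolerance = 1e-6)
  expect_equal(cap$max_uptake, 1, tolerance = 1e-6)

  # glucose supplementation never lowers the achievable degradation rate
  cap2 <- degradation_capacity(toy, atrazine_media(atz = 1,
                                                   extra = c(EX_glc = 10)),
                               "EX_atz")
  expect_gte(cap2$max_uptake, cap$max_uptake - 1e-6)

  # closed exchange: nothing can flow
  cap3 <- degradation_capacity(toy, atrazine_media(atz = 0), "EX_atz")
  expect_equal(c(cap3$min_uptake, cap3$max_uptake), c(0, 0))
  expect_error(degradation_capacity(toy, med, "TrzN"), "exchange")
})
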