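test_that("supplement screen ranks candidates and never falls below base", {
  toy <- pathway_toy()
  base <- atrazine_media(atz = 1)
  res <- supplement_screen(toy, base, c("EX_glc", "EX_nh4", "EX_h2"),
                           supplement_bound = 10)
  expect_s3_class(res, "pa_screen")
  expect_equal(res$exchange[1], "EX_glc")  # extra carbon helps most
  base_mu <- attr(res, "base_mu")
  expect_true(all(res$mu >= base_mu - 1e-9))
  # supplement atom counts come from the exchanged species formula
  expect_equal(res$carbon[res$exchange == "EX_glc"], 6)
  expect_equal(res$nitrogen[res$exchange == "EX_nh4"], 1)

  # a candidate already in the base medium leaves the optimum unchanged
  again <- supplement_screen(toy, base, "EX_atz", supplement_bound = 1)
  expect_equal(again$mu, base_mu, tolerance = 1e-9)

  # releasing the single bottleneck recovers the analytic optimum
  t1 <- make_toy_model("TOY-1")
  scr <- supplement_screen(t1, media(c(EX_glc = 10)), "EX_nh4",
                           supplement_bound = 10)
  expect_equal(attr(scr, "base_mu"), 0)
  expect_equal(scr$mu, 10, tolerance = 1e-9)

  expect_error(supplement_screen(t1, media(), "T_glc"), "exchange")
})

test_that("classification reproduces the published amino-acid labels", {
  # printed screen: Ile 11.3, His 7.4, Met 1.4 h^-1 against a 13 h^-1 top
  screen <- tibble::tibble(exchange = c("EX_ile", "EX_his", "EX_met",
                                        "EX_best"),
                           mu = c(11.3, 7.4, 1.4, 13))
  cls <- classify_supplements(screen)
  got <- setNames(as.character(cls$class), cls$exchange)
  expect_equal(got[["EX_ile"]], "high")
  expect_equal(got[["EX_his"]], "moderate")
  expect_equal(got[["EX_met"]], "low")

  # scale invariance and degenerate cases
  for (k in c(0.01, 3, 1000)) {
    scaled <- classify_supplements(dplyr::mutate(screen, mu = mu * k))
    expect_equal(as.character(scaled$class), as.character(cls$class))
  }
  allsame <- classify_supplements(tibble::tibble(exchange = letters[1:3],
                                                 mu = rep(2.2, 3)))
  expect_true(all(allsame$class == "high"))
  single <- classify_supplements(tibble::tibble(exchange = "a", mu = 0.1))
  expect_equal(as.character(single$class), "high")
  expect_error(classify_supplements(tibble::tibble(exchange = character(0),
                                                   mu = numeric(0))),
               "Empty")
})

test_that("gradient surface equals the analytic bottleneck and is monotone", {
  t1 <- make_toy_model("TOY-1")
  surf <- gradient_scan(t1, media(), "EX_glc", "EX_nh4", 0:10, 0:10)
  expect_equal(surf$mu, pmin(surf$bound1, 2 * surf$bound2), tolerance = 1e-9)
  # zero carbon or zero nitrogen row is identically zero
  expect_true(all(surf$mu[surf$bound1 == 0] == 0))
  expect_true(all(surf$mu[surf$bound2 == 0] == 0))
  # monotone along both axes
  wide <- tidyr::pivot_wider(surf, names_from = "bound2", values_from = "mu")
  Z <- as.matrix(wide[, -1])
  expect_true(all(apply(Z, 1, function(x) all(diff(x) >= -1e-9))))
  expect_true(all(apply(Z, 2, function(x) all(diff(x) >= -1e-9))))
  expect_error(gradient_scan(t1, media(), "EX_glc", "EX_nh4", c(3, 1), 0:2),
               "ascending")
})

test_that("ammonium axis is flat when atrazine covers the nitrogen demand", {
  toy <- pathway_toy()
  surf <- gradient_scan(toy, atrazine_media(atz = 5), "EX_glc", "EX_nh4",
                        c(0, 2, 4), c(0, 2, 4))
  wide <- tidyr::pivot_wider(surf, names_from = "bound2", values_from = "mu")
  Z <- as.matrix(wide[, -1])
  # glucose (rows) increases growth; ammonium (columns) adds nothing
  expect_true(all(diff(Z[, 1]) > 1e-9))
  expect_true(all(abs(Z[, 2] - Z[, 1]) < 1e-9))
  expect_true(all(abs(Z[, 3] - Z[, 1]) < 1e-9))
})

test_that("C:N ratios of the screen compounds recompute from formulas", {
  expect_equal(cn_ratio("C6H13NO2"), tibble::tibble(carbon = 6, nitrogen = 1))
  expect_equal(cn_ratio("C6H9N3O2"), tibble::tibble(carbon = 6, nitrogen = 3))
  expect_equal(cn_ratio("C5H11NO2S"), tibble::tibble(carbon = 5, nitrogen = 1))
  expect_equal(cn_ratio("H2O"), tibble::tibble(carbon = 0, nitrogen = 0))
})

test_that("equimolar-nitrogen doses recompute the in vitro design", {
  atz <- compound("C8H14ClN5", mw = 215.68, conc = 30)
  # printed: histidine 36, ammonium chloride 37 mg/l (exact at rounding)
  expect_equal(equimolar_nitrogen_dose(atz, compound("C6H9N3O2",
                                                     mw = 155.15))$dose, 36)
  expect_equal(equimolar_nitrogen_dose(atz, compound("NH4Cl",
                                                     mw = 53.49))$dose, 37)
  # identity: atrazine against itself returns its own concentration
  self <- equimolar_nitrogen_dose(atz, compound("C8H14ClN5", mw = 215.68))
  expect_equal(self$dose_exact, 30, tolerance = 1e-12)
  # isoleucine / methionine / amines within 2% of the printed 92/103/31.1/40.8
  ile <- equimolar_nitrogen_dose(atz, compound("C6H13NO2", mw = 131.17))
  met <- equimolar_nitrogen_dose(atz, compound("C5H11NO2S", mw = 149.21))
  eth <- equimolar_nitrogen_dose(atz, compound("C2H7N", mw = 45.08),
                                 digits = 1)
  iso <- equimolar_nitrogen_dose(atz, compound("C3H9N", mw = 59.11),
                                 digits = 1)
  expect_lt(abs(ile$dose_exact - 92) / 92, 0.02)
  expect_lt(abs(met$dose_exact - 103) / 103, 0.02)
  expect_lt(abs(eth$dose_exact - 31.1) / 31.1, 0.02)
  expect_lt(abs(iso$dose_exact - 40.8) / 40.8, 0.02)
  # a nitrogen-free target cannot be matched
  expect_error(equimolar_nitrogen_dose(atz, compound("C6H12O6")),
               "nitrogen")
})

test_that("dose arithmetic composes along chains of compounds", {
  a <- compound("C8H14ClN5", mw = 215.68, conc = 30)
  b <- compound("C6H9N3O2", mw = 155.15)
  c3 <- compound("NH4Cl", mw = 53.49)
  ab <- equimolar_nitrogen_dose(a, b)$dose_exact
  bc <- equimolar_nitrogen_dose(compound(b$formula, mw = b$mw, conc = ab),
                                c3)$dose_exact
  ac <- equimolar_nitrogen_dose(a, c3)$dose_exact
  expect_equal(bc, ac, tolerance = 1e-10)
})
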