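test_that("uptake bounds follow min(cap, pool / (X dt))", {
  cfg <- dynamic_config(c(EX_glc = 50), uptake_cap = 1, dt = 1)
  b <- compute_uptake_bounds(c(EX_glc = 50), 1, cfg)
  expect_equal(b$uptake, 1)               # cap binds
  b <- compute_uptake_bounds(c(EX_glc = 0.5), 1, cfg)
  expect_equal(b$uptake, 0.5)             # pool binds
  b <- compute_uptake_bounds(c(EX_glc = 0), 1, cfg)
  expect_equal(b$uptake, 0)               # exhausted
  b <- compute_uptake_bounds(c(EX_glc = 50), 100, cfg)
  expect_equal(b$uptake, 0.5)             # population dilutes the pool
  expect_error(compute_uptake_bounds(c(EX_glc = 1), 0, cfg), "positive")
  expect_error(compute_uptake_bounds(c(EX_glc = -2), 1, cfg), "invariant")
})

test_that("TOY-1 timecourse matches the hand-computed recurrence", {
  t1 <- make_toy_model("TOY-1")
  traj <- simulate_timecourse(
    t1, dynamic_config(c(EX_glc = 50, EX_nh4 = 50)))
  # while the 1-unit cap binds the population doubles every tick
  expect_equal(traj$states$biomass[1:6], c(1, 2, 4, 8, 16, 32))
  expect_equal(traj$states$mu[1:5], rep(1, 5))
  # glucose depletion: 50 minus the cumulative consumption of the recurrence
  glc <- degradation_curve(traj, "EX_glc")
  expect_equal(glc$amount, c(50, 49, 47, 43, 35, 19, 0))
  # all 50 substrate units convert at yield 1: X_final = X0 + Y * S0
  expect_equal(tail(traj$states$biomass, 1), 51, tolerance = 1e-9)
  # nitrogen is non-limiting: half a unit per biomass unit
  nh4 <- degradation_curve(traj, "EX_nh4")
  expect_equal(tail(nh4$amount, 1), 50 - 0.5 * 50, tolerance = 1e-9)
})

test_that("geometric growth matches the closed form while the cap binds", {
  t1 <- make_toy_model("TOY-1")
  cfg <- dynamic_config(c(EX_glc = 1e5, EX_nh4 = 1e5), uptake_cap = 1,
                        dt = 1, max_cycles = 12)
  traj <- simulate_timecourse(t1, cfg)
  mu_cap <- 1  # biomass coefficient on glucose is 1, so mu = cap
  expect_equal(traj$states$biomass,
               (1 + mu_cap * cfg$dt)^(traj$states$time / cfg$dt),
               tolerance = 1e-9)
})

test_that("pools stay non-negative and consumption is conservative", {
  for (model_media in list(
    list(make_toy_model("TOY-1"), c(EX_glc = 13, EX_nh4 = 4)),
    list(pathway_toy(),
         c(EX_atz = 30, EX_h2o = 1e6, EX_h = 1e6, EX_pi = 50)))) {
    traj <- simulate_timecourse(model_media[[1]],
                                dynamic_config(model_media[[2]]))
    expect_true(all(traj$pools$amount >= -1e-9))
    expect_true(all(diff(traj$states$biomass) >= -1e-9))
    for (ex in names(model_media[[2]])) {
      curve <- degradation_curve(traj, ex)
      consumed <- curve$amount[1] - tail(curve$amount, 1)
      expect_lte(consumed, model_media[[2]][[ex]] + 1e-9)
    }
  }
})

test_that("empty pools stall immediately", {
  t1 <- make_toy_model("TOY-1")
  traj <- simulate_timecourse(t1, dynamic_config(c(EX_glc = 0, EX_nh4 = 0)))
  expect_equal(nrow(traj$states), 1)
  expect_equal(traj$states$biomass, 1)
  expect_equal(traj$states$mu, 0)
})

test_that("doubling substrate pools at least doubles the biomass gain", {
  t1 <- make_toy_model("TOY-1")
  gain <- function(s0) {
    traj <- simulate_timecourse(t1, dynamic_config(c(EX_glc = s0,
                                                     EX_nh4 = 1e4)))
    tail(traj$states$biomass, 1) - 1
  }
  for (s0 in c(5, 20, 50)) {
    expect_gte(gain(2 * s0), 2 * gain(s0) - 1e-6)
  }
})

test_that("cyanuric acid accumulates mole-for-mole with atrazine consumed", {
  toy <- pathway_toy()
  traj <- simulate_timecourse(
    toy, dynamic_config(c(EX_atz = 30, EX_h2o = 1e6, EX_h = 1e6,
                          EX_pi = 50)))
  atz <- degradation_curve(traj, "EX_atz")
  expect_true(all(diff(atz$amount) <= 1e-9))  # monotone non-increasing
  consumed <- atz$amount[1] - tail(atz$amount, 1)
  expect_gt(consumed, 0)
  cya <- traj$pools[traj$pools$exchange == "EX_cya", ]
  expect_equal(tail(cya$amount, 1), consumed, tolerance = 1e-6)
})

test_that("glucose supplementation speeds up atrazine depletion", {
  toy <- pathway_toy()
  base_pools <- c(EX_atz = 30, EX_h2o = 1e6, EX_h = 1e6, EX_pi = 50)
  alone <- simulate_timecourse(toy, dynamic_config(base_pools))
  with_glc <- simulate_timecourse(
    toy, dynamic_config(c(base_pools, EX_glc = 30)))
  remaining <- function(traj, t) {
    cv <- degradation_curve(traj, "EX_atz")
    cv$amount[findInterval(t, cv$time)]
  }
  # growth is faster with glucose...
  t_common <- min(max(alone$states$time), max(with_glc$states$time))
  expect_gt(
    with_glc$states$biomass[with_glc$states$time == t_common],
    alone$states$biomass[alone$states$time == t_common])
  # ...and atrazine disappears sooner at the shared observation time
  expect_lt(remaining(with_glc, t_common), remaining(alone, t_common))
})

test_that("phosphate limitation slows growth and atrazine degradation", {
  toy <- pathway_toy()
  pools <- function(pi) c(EX_atz = 30, EX_h2o = 1e6, EX_h = 1e6, EX_pi = pi)
  high <- simulate_timecourse(toy, dynamic_config(pools(50)))
  low <- simulate_timecourse(toy, dynamic_config(pools(0.5)))
  expect_lt(tail(low$states$biomass, 1), tail(high$states$biomass, 1))
  expect_gt(tail(degradation_curve(low, "EX_atz")$amount, 1),
            tail(degradation_curve(high, "EX_atz")$amount, 1))
})

test_that("degradation curves error on untracked targets", {
  t1 <- make_toy_model("TOY-1")
  traj <- simulate_timecourse(t1, dynamic_config(c(EX_glc = 5, EX_nh4 = 5)))
  expect_error(degradation_curve(traj, "EX_missing"), "not tracked")
})
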