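test_that("reference transit probability follows the membrane rule", {
  expect_equal(transit_probability_reference(0.5, 0, 1.2), 0)
  expect_equal(transit_probability_reference(0.5, 1e12, 1.2), 1, tolerance = 1e-10)
  dx <- sqrt(2 * 0.5 * 1.5)
  expect_equal(transit_probability_reference(0.5, 0.05, dx),
               2 * 0.05 * dx / (0.5 + 2 * 0.05 * dx))
  expect_equal(transit_probability_reference(0.5, 0.05, dx), 0.1967, tolerance = 3e-4)
  expect_error(transit_probability_reference(0.5, 0.05, -1), "non-negative")
  expect_error(transit_probability_reference(0, 0.05, 1), "positive")
})

test_that("hybrid transit probability has the right branches and limits", {
  # no diffusivity step: identical to the reference rule
  dx <- seq(0, 3, by = 0.25)
  expect_equal(transit_probability_hybrid(0.8, 0.8, 0.07, dx),
               transit_probability_reference(0.8, 0.07, dx))
  # into higher diffusivity: reduces to the reference rule exactly
  expect_equal(transit_probability_hybrid(0.5, 2.5, 0.05, dx),
               transit_probability_reference(0.5, 0.05, dx))
  # infinite permeability, into lower diffusivity: the diffusivity-step
  # acceptance of the interface reflection condition
  expect_equal(transit_probability_hybrid(2.5, 0.5, 1e12, 1.5), sqrt(0.2),
               tolerance = 1e-10)
  # impermeable membrane blocks regardless of the diffusivity step
  expect_equal(transit_probability_hybrid(2.5, 0.5, 0, 1.5), 0)
})

test_that("hybrid rule balances directional crossing rates at uniform density", {
  # At uniform density the mean L->R and R->L transmission rates per step
  # must be equal for ANY dt. Semi-analytical oracle: the walkers within one
  # step of the barrier attempt with dx_i ~ U(0, step_i), so the rate from
  # side i is (step_i / 2) * E[p_t(dx_i)]; compare the two sides by
  # quadrature.
  D_i <- 2.5; D_j <- 0.5; kap <- 0.7; dt <- 3
  rate <- function(D_from, D_to) {
    step <- sqrt(2 * D_from * dt)
    stats::integrate(function(u) transit_probability_hybrid(D_from, D_to, kap, u),
                     0, step)$value / 2
  }
  expect_equal(rate(D_i, D_j), rate(D_j, D_i), tolerance = 1e-10)
  # the reference rule only balances to first order in kappa
  rate_ref <- function(D_from) {
    step <- sqrt(2 * D_from * dt)
    stats::integrate(function(u) transit_probability_reference(D_from, kap, u),
                     0, step)$value / 2
  }
  expect_gt(abs(rate_ref(D_i) - rate_ref(D_j)), 0.05 * rate_ref(D_j))
})

test_that("seed_walkers honours the seeding modes", {
  dom <- benchmark_domain()
  expect_equal(seed_walkers("delta:24.75", 3, build_domain(49.5, 1)),
               rep(24.75, 3))
  set.seed(1)
  xi <- seed_walkers("interval:6,14", 500, dom)
  expect_true(all(xi >= 6 & xi <= 14))
  set.seed(1)
  xf <- seed_walkers("uniform_full", 4e4, dom)
  expect_lt(abs(mean(xf) - 20), 3 * (40 / sqrt(12)) / sqrt(4e4))
  expect_error(seed_walkers("interval:30,50", 10, dom), "outside")
  expect_error(seed_walkers("delta:99", 10, dom), "outside")
})

test_that("single steps reflect and transmit as the split-step rules dictate", {
  # All walkers at x = 19, one step of length 2 (D = 2, dt = 1). Rightward
  # movers hit the barrier at 20 with dx_i = 1, dx_j = 1.
  dom_block <- build_domain(c(20, 20), c(2, 0.5), 0)      # kappa = 0: reflect
  run <- run_simulation(dom_block, sim_config(1, 1, 5e3, "delta:19",
                                              model = "hybrid", seed = 3))
  expect_setequal(round(run$x, 10), c(17, 19))            # free left / reflected
  expect_true(all(run$comp == 1L))

  dom_open <- build_domain(c(20, 20), c(2, 0.5), 1e12)    # kappa -> inf
  run <- run_simulation(dom_open, sim_config(1, 1, 5e3, "delta:19",
                                             model = "hybrid", seed = 3))
  # transmit w.p. sqrt(0.25) = 0.5: x = 20 + 1 * sqrt(0.5/2) = 20.5
  expect_setequal(round(run$x, 10), c(17, 19, 20.5))
  expect_equal(sort(unique(run$comp[round(run$x, 10) == 20.5])), 2L)

  # domain ends always reflect: walkers at 1 stepping left end at 1
  run <- run_simulation(build_domain(40, 2), sim_config(1, 1, 2e3, "delta:1", seed = 4))
  expect_setequal(round(run$x, 10), c(1, 3))
})

test_that("walkers are conserved and confined", {
  dom <- benchmark_domain()
  run <- run_simulation(dom, sim_config(5, 500, 2e3, "uniform_full",
                                        model = "hybrid", seed = 11,
                                        record_flux = TRUE, record_counts = TRUE))
  expect_length(run$x, 2e3)
  expect_true(all(run$x >= 0 & run$x <= 40))
  expect_true(all(rowSums(run$counts) == 2e3))
  expect_true(all(run$cross_lr >= 0 & run$cross_lr <= 2e3))
})

test_that("impermeable internal membranes are never crossed", {
  dom <- benchmark_domain(kappa = 0)
  run <- run_simulation(dom, sim_config(5, 500, 5e3, "interval:0,20",
                                        model = "hybrid", seed = 2,
                                        record_flux = TRUE))
  expect_equal(sum(run$cross_lr) + sum(run$cross_rl), 0)
  expect_true(all(run$x <= 20))
})

test_that("reference and hybrid runs are bit-identical when D is uniform", {
  dom <- build_domain(c(15, 25), c(1.3, 1.3), 0.4)
  a <- run_simulation(dom, sim_config(2, 200, 5e3, "uniform_full",
                                      model = "hybrid", seed = 7, record_flux = TRUE))
  b <- run_simulation(dom, sim_config(2, 200, 5e3, "uniform_full",
                                      model = "reference", seed = 7, record_flux = TRUE))
  expect_identical(a$x, b$x)
  expect_identical(a$cross_lr, b$cross_lr)
})

test_that("runs are reproducible from the seed", {
  dom <- benchmark_domain()
  cfg <- sim_config(1.5, 150, 2e3, "delta:10", model = "hybrid", seed = 123,
                    record_flux = TRUE)
  a <- run_simulation(dom, cfg)
  b <- run_simulation(dom, cfg)
  expect_identical(a$x, b$x)
  expect_identical(a$cross_lr, b$cross_lr)
})

test_that("free diffusion reproduces the displacement variance 2 D t", {
  dom <- build_domain(4000, 1.7)
  run <- run_simulation(dom, sim_config(5, 500, 1e5, "delta:2000", seed = 31))
  v <- mean((run$x - run$x0)^2)
  expect_equal(v, 2 * 1.7 * 500, tolerance = 0.01)
})

test_that("hybrid model holds the uniform steady state; per-step crossings balance", {
  dom <- benchmark_domain()
  run <- run_simulation(dom, sim_config(10, 800, 2e5, "uniform_full",
                                        model = "hybrid", seed = 17,
                                        record_flux = TRUE))
  f <- compartment_fractions(run)
  expect_lt(abs(f[1L] - 0.5), 3 * fraction_sd(2e5))
  # detailed balance: total L->R vs R->L transmissions agree within
  # 3 sigma of sqrt(2 * mean count)
  nlr <- sum(run$cross_lr); nrl <- sum(run$cross_rl)
  expect_lt(abs(nlr - nrl), 3 * sqrt(2 * (nlr + nrl) / 2))
})

test_that("dt above the domain limit is rejected, not clamped", {
  dom <- benchmark_domain()   # dt_max = 80
  expect_error(run_simulation(dom, sim_config(81, 810, 10)), "exceeds the domain limit")
})

test_that("density histograms are density-normalised and conserve counts", {
  dom <- build_domain(40, 1)
  h <- density_histogram(rep(5.5, 100), 2, dom)
  expect_equal(h$density[h$center == 5], 0.5)
  expect_equal(sum(h$density * h$width), 1)
  expect_equal(sum(h$count), 100)

  set.seed(2)
  x <- runif(2e5, 0, 40)
  h <- density_histogram(x, 2, dom)
  expect_equal(h$density, rep(0.025, 20), tolerance = 0.03)
  expect_equal(sum(h$count), 2e5)
})

test_that("snapshots are stored at the requested times", {
  dom <- benchmark_domain()
  run <- run_simulation(dom, sim_config(5, 100, 100, "delta:10", seed = 1,
                                        snapshot_times = c(25, 50)))
  expect_named(run$snapshots, c("25", "50"))
  expect_length(run$snapshots[["25"]], 100)
})
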