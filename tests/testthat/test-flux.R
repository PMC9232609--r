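test_that("analytical flux vanishes for stationary or impermeable configurations", {
  sp <- benchmark_spectrum()
  fa <- analytical_flux(sp, 1, c(1, 10, 100), "uniform_full")
  expect_equal(fa$J, rep(0, 3), tolerance = 1e-12)
  dom0 <- benchmark_domain(kappa = 0)
  sp0 <- find_eigenvalues(dom0, lambda_max = 5, scan_points = 5e3)
  f0 <- analytical_flux(sp0, 1, c(1, 10), "interval:0,20")
  expect_equal(f0$J, c(0, 0))
})

test_that("transient flux into the empty compartment stays positive with one peak", {
  sp <- benchmark_spectrum()
  tt <- seq(4, 1000, by = 1)   # below ~4 ms the truncated expansion dribbles
  fa <- analytical_flux(sp, 1, tt, "delta:10")
  expect_true(all(fa$J > 0))
  k <- which.max(fa$J)
  expect_true(all(diff(fa$J[1:k]) > 0))
  expect_true(all(diff(fa$J[k:length(tt)]) < 0))
  # cumulative flux approaches 1/2 (delta expansions converge slowly in the
  # mode index, hence the looser tolerance than the uniform-IC case)
  expect_equal(fa$cumfun(5e4), 0.5, tolerance = 1e-4)
  fu <- analytical_flux(sp, 1, 1, "interval:0,20")
  expect_equal(fu$cumfun(5e4), 0.5, tolerance = 1e-7)
})

test_that("analytical cumulative flux equals the compartment mass transfer", {
  # two independent eigen computations: time-integrated membrane flux vs the
  # right-compartment mass from the propagator
  sp <- benchmark_spectrum()
  x <- seq(20, 40, length.out = 2001)
  for (t in c(50, 400)) {
    mass_right <- trapz(x, propagator_uniform(sp, x, t, c(0, 20))$U)
    fa <- analytical_flux(sp, 1, t, "interval:0,20")
    expect_equal(fa$cumulative, mass_right, tolerance = 1e-6)
  }
})

test_that("numerical flux normalisation and conservation are exact", {
  dom <- benchmark_domain(kappa = 0.5)
  run <- run_simulation(dom, sim_config(5, 500, 2e4, "interval:0,20",
                                        model = "hybrid", seed = 9,
                                        record_flux = TRUE, record_counts = TRUE))
  fn <- numerical_flux(run, 1)
  expect_equal(fn$J, (run$cross_lr[, 1] - run$cross_rl[, 1]) / (2e4 * 5))
  # cumulative flux == fraction currently right of the interface, every step
  frac_right <- run$counts[, 2] / 2e4
  expect_equal(fn$cumulative, frac_right)
  # long-time limit 0.5 with all-left seeding (kappa = 0.5 mixes fast)
  run2 <- run_simulation(dom, sim_config(5, 5000, 2e4, "interval:0,20",
                                         model = "hybrid", seed = 10,
                                         record_flux = TRUE))
  f2 <- numerical_flux(run2, 1)
  expect_lt(abs(f2$cumulative[length(f2$cumulative)] - 0.5),
            3 * fraction_sd(2e4))
})

test_that("window averaging is identity at the step, exact for constants, total mean for T", {
  series <- structure(list(times = seq(2, 100, by = 2), J = rep(0.3, 50),
                           cumulative = cumsum(rep(0.6, 50)), interface = 1L,
                           source = "numerical", Jfun = NULL, cumfun = NULL,
                           dt = 2), class = "pw_flux_series")
  expect_identical(time_averaged_flux(series, 2), series)
  w <- time_averaged_flux(series, 20)
  expect_equal(w$J, rep(0.3, 5))
  tot <- time_averaged_flux(series, 100)
  expect_equal(tot$J, series$cumulative[50] / 100)
  expect_error(time_averaged_flux(series, 3), "multiple")
})

test_that("endpoint and global errors are zero for identical series and signed otherwise", {
  sp <- benchmark_spectrum()
  tt <- seq(5, 500, by = 5)
  fa <- analytical_flux(sp, 1, tt, "interval:0,20")
  fa_num <- fa; fa_num$source <- "numerical"
  expect_equal(endpoint_relative_error(fa_num, fa), 0)
  expect_equal(global_error(fa_num, fa), 0)
  shrunk <- fa_num; shrunk$cumulative <- 0.9 * fa$cumulative
  expect_equal(endpoint_relative_error(shrunk, fa), -0.1)
  expect_equal(global_error(shrunk, fa), 0.1, tolerance = 1e-12)
  short <- fa_num; short$times <- fa$times - 5
  expect_error(endpoint_relative_error(short, fa), "different times")
})

test_that("Monte Carlo cumulative flux tracks the eigen solution within noise", {
  dom <- benchmark_domain()
  sp <- benchmark_spectrum()
  run <- run_simulation(dom, sim_config(2, 400, 5e4, "interval:0,20",
                                        model = "hybrid", seed = 21,
                                        record_flux = TRUE))
  fn <- numerical_flux(run, 1)
  fa <- analytical_flux(sp, 1, fn$times, "interval:0,20")
  expect_lt(abs(fn$cumulative[200] - fa$cumulative[200]),
            4 * fraction_sd(5e4) + 0.02 * fa$cumulative[200])
})

test_that("peak time refines the analytic maximiser and is exact on a calculus case", {
  tt <- seq(0.05, 10, by = 0.05)
  synth <- structure(list(times = tt, J = tt * exp(-tt),
                          cumulative = cumsum(tt * exp(-tt)) * 0.05,
                          interface = 1L, source = "analytical",
                          Jfun = function(t) t * exp(-t), cumfun = NULL,
                          dt = NULL), class = "pw_flux_series")
  expect_equal(peak_time(synth), 1, tolerance = 1e-2)
  # discrete ties: earliest maximiser
  disc <- structure(list(times = 1:5, J = c(0, 1, 1, 0.5, 0), cumulative = cumsum(c(0, 1, 1, 0.5, 0)),
                         interface = 1L, source = "numerical", Jfun = NULL,
                         cumfun = NULL, dt = 1), class = "pw_flux_series")
  expect_equal(peak_time(disc), 2)
  zero <- disc; zero$J <- rep(0, 5)
  expect_error(peak_time(zero), "undefined")
})
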