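# Shared fixtures. The benchmark is the two-compartment domain used
# throughout the package documentation: two 20 um compartments with
# D_L = 0.5, D_R = 2.5 um^2/ms and an internal membrane kappa = 0.05 um/ms.

benchmark_domain <- function(kappa = 0.05) {
  build_domain(c(20, 20), c(0.5, 2.5), kappa)
}

# Cached benchmark spectrum (shared across test files; building it once
# keeps the suite fast).
benchmark_spectrum <- local({
  sp <- NULL
  function() {
    if (is.null(sp)) sp <<- find_eigenvalues(benchmark_domain(),
                                             lambda_max = 200,
                                             scan_points = 5e4)
    sp
  }
})

# Monte Carlo standard deviation of a walker fraction at p ~ 0.5.
fraction_sd <- function(Np) 0.5 / sqrt(Np)

# Trapezoidal integral on a uniform or non-uniform grid.
trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
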