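#' Characteristic function of the layered diffusion operator
#'
#' Separation of variables in the layered diffusion problem reduces each
#' compartment to a Helmholtz equation `D_i u'' + lambda u = 0`, whose local
#' solution is `A cos(alpha_i (x - b_i)) + B sin(alpha_i (x - b_i))` with
#' `alpha_i = sqrt(lambda / D_i)`. Starting from the sealed left end
#' (`(A, B) = (1, 0)`), the coefficient pair is propagated compartment by
#' compartment by enforcing, at every internal membrane, flux continuity and
#' the permeability jump condition
#' `D_i u'|_L = D_j u'|_R = kappa (u|_R - u|_L)`.
#' The returned scalar is the residual of the sealed right-end condition
#' `D_m u'(b_m)`; its sign changes exactly at the eigenvalues.
#'
#' Each propagated coefficient pair is rescaled to unit norm (a strictly
#' positive factor) to avoid overflow; the sign of the residual is preserved.
#' An internal interface with `kappa = 0` decouples the domain: the
#' propagation then carries only the incoming flux, and the zero set becomes
#' the union of the sub-domain spectra.
#'
#' @param domain a `pw_domain`.
#' @param lambda positive eigenvalue candidates (1/ms); vectorised. The
#'   `lambda = 0` constant mode is handled analytically elsewhere, not here.
#' @return numeric vector of signed residuals, one per `lambda`.
#' @export
characteristic_function <- function(domain, lambda) {
  assert_domain(domain)
  if (any(lambda <= 0)) stop("lambda must be positive (the zero mode is analytic)")
  m <- length(domain$D)
  L <- domain$lengths
  A <- rep(1, length(lambda))
  B <- rep(0, length(lambda))
  for (i in seq_len(m)) {
    alpha <- sqrt(lambda / domain$D[i])
    cc <- cos(alpha * L[i])
    ss <- sin(alpha * L[i])
    uL <- A * cc + B * ss
    fl <- domain$D[i] * alpha * (B * cc - A * ss)   # D_i u'(b_i^-)
    if (i == m) {
      kap <- domain$kappa[m + 1L]
      return(fl + kap * uL)   # sealed end: kappa = 0 reduces to D_m u'(b_m)
    }
    kap <- domain$kappa[i + 1L]
    alpha_j <- sqrt(lambda / domain$D[i + 1L])
    if (kap > 0) {
      A <- uL + fl / kap                     # u|_R = u|_L + flux / kappa
      B <- fl / (domain$D[i + 1L] * alpha_j) # D_j u'|_R = flux
    } else {
      A <- fl                                # decoupled: carry the flux residual
      B <- rep(0, length(lambda))
    }
    r <- sqrt(A^2 + B^2)
    r[r == 0] <- 1
    A <- A / r
    B <- B / r
  }
}

# Propagate unscaled mode coefficients for a single eigenvalue.
# Returns list(A, B) of per-compartment coefficients (un-normalised).
mode_coefficients <- function(domain, lambda) {
  m <- length(domain$D)
  L <- domain$lengths
  A <- numeric(m); B <- numeric(m)
  A[1L] <- 1; B[1L] <- 0
  if (lambda == 0) {
    A[] <- 1
    return(list(A = A, B = B))
  }
  for (i in seq_len(m - 1L)) {
    alpha <- sqrt(lambda / domain$D[i])
    cc <- cos(alpha * L[i]); ss <- sin(alpha * L[i])
    uL <- A[i] * cc + B[i] * ss
    fl <- domain$D[i] * alpha * (B[i] * cc - A[i] * ss)
    kap <- domain$kappa[i + 1L]
    alpha_j <- sqrt(lambda / domain$D[i + 1L])
    if (kap > 0) {
      A[i + 1L] <- uL + fl / kap
      B[i + 1L] <- fl / (domain$D[i + 1L] * alpha_j)
    } else {
      A[i + 1L] <- fl
      B[i + 1L] <- 0
    }
  }
  list(A = A, B = B)
}

# Closed-form squared L2 norm of a piecewise mode over the domain.
mode_norm2 <- function(domain, lambda, coef) {
  m <- length(domain$D)
  L <- domain$lengths
  total <- 0
  for (i in seq_len(m)) {
    A <- coef$A[i]; B <- coef$B[i]
    if (lambda == 0) {
      total <- total + A^2 * L[i]
    } else {
      alpha <- sqrt(lambda / domain$D[i])
      s2 <- sin(2 * alpha * L[i]); s1 <- sin(alpha * L[i])
      total <- total +
        (A^2 + B^2) * L[i] / 2 +
        (A^2 - B^2) * s2 / (4 * alpha) +
        A * B * s1^2 / alpha
    }
  }
  total
}

#' Eigen-decomposition of a layered domain
#'
#' Finds all eigenvalues of the layered diffusion operator on
#' `(0, lambda_max]` as bracketed sign changes of [characteristic_function()]
#' on a grid uniform in `sqrt(lambda)` (the asymptotic eigenvalue density is
#' uniform in `sqrt(lambda)`), refines each root to relative tolerance
#' `1e-12`, and prepends the analytic `lambda = 0` constant mode. Each mode is
#' reconstructed as per-compartment `(A, B)` coefficients and normalised so
#' that its squared integral over the domain equals 1.
#'
#' @param domain a `pw_domain`.
#' @param lambda_max scan upper bound (1/ms). Default 500.
#' @param n_max maximum number of modes kept, including the constant mode.
#'   Default 1000.
#' @param scan_points number of scan grid points. Default 1e5.
#' @return an object of class `pw_spectrum`: `lambda` (ascending), matrices
#'   `A`, `B` (modes x compartments, normalised), and the `domain`.
#' @export
find_eigenvalues <- function(domain, lambda_max = 500, n_max = 1000,
                             scan_points = 1e5) {
  assert_domain(domain)
  if (lambda_max <= 0) stop("lambda_max must be positive")
  u <- seq(sqrt(lambda_max) / scan_points, sqrt(lambda_max), length.out = scan_points)
  lam_grid <- u^2
  f <- characteristic_function(domain, lam_grid)
  roots <- numeric(0)
  sgn <- sign(f)
  # exact zeros on the grid are roots themselves
  hit <- which(sgn == 0)
  roots <- c(roots, lam_grid[hit])
  chg <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  for (k in chg) {
    r <- stats::uniroot(function(l) characteristic_function(domain, l),
                        lower = lam_grid[k], upper = lam_grid[k + 1L],
                        f.lower = f[k], f.upper = f[k + 1L],
                        tol = 1e-12 * lam_grid[k + 1L])
    roots <- c(roots, r$root)
  }
  roots <- sort(roots)
  # missed-root check against the Weyl count: the number of eigenvalues below
  # lambda is asymptotically sqrt(lambda) * sum(L_i / sqrt(D_i)) / pi, exact
  # to within about one mode per compartment (interlacing). A clear deficit
  # means the scan grid skipped sign changes.
  if (length(roots) > 12L) {
    weyl <- sqrt(lambda_max) * sum(domain$lengths / sqrt(domain$D)) / pi
    if (length(roots) < weyl - (length(domain$D) + 2L))
      warning("possible missed eigenvalue(s): found ", length(roots),
              " roots below lambda_max but ~", round(weyl),
              " expected; increase scan_points")
  }
  lambda <- c(0, roots)
  if (length(lambda) > n_max) lambda <- lambda[seq_len(n_max)]
  m <- length(domain$D)
  N <- length(lambda)
  Amat <- matrix(0, N, m); Bmat <- matrix(0, N, m)
  for (n in seq_len(N)) {
    coef <- mode_coefficients(domain, lambda[n])
    nrm <- sqrt(mode_norm2(domain, lambda[n], coef))
    Amat[n, ] <- coef$A / nrm
    Bmat[n, ] <- coef$B / nrm
  }
  structure(
    list(lambda = lambda, A = Amat, B = Bmat, domain = domain,
         lambda_max = lambda_max, scan_points = scan_points),
    class = "pw_spectrum"
  )
}

#' @export
print.pw_spectrum <- function(x, ...) {
  cat("Layered-diffusion eigen spectrum:", length(x$lambda), "modes,",
      sprintf("lambda in [0, %.4g] 1/ms\n", max(x$lambda)))
  invisible(x)
}

assert_spectrum <- function(spectrum) {
  if (!inherits(spectrum, "pw_spectrum")) stop("expected a 'pw_spectrum' object")
  invisible(spectrum)
}

#' Evaluate a normalised eigenmode
#'
#' Piecewise evaluation of mode `n` at positions `x`. Inside compartments the
#' mode is smooth; at internal membranes it jumps by `flux / kappa`. Positions
#' exactly on a barrier are evaluated one-sidedly in the right compartment
#' (stateless convention); use `side = "left"` to get the left limit.
#'
#' @param spectrum a `pw_spectrum`.
#' @param n mode index (1 is the constant mode).
#' @param x numeric vector of positions (um) inside the domain.
#' @param side `"right"` (default) or `"left"`: which one-sided limit to take
#'   for positions exactly on an internal barrier.
#' @return numeric vector of mode values (1/sqrt(um)).
#' @export
eigenmode_eval <- function(spectrum, n, x, side = c("right", "left")) {
  assert_spectrum(spectrum)
  side <- match.arg(side)
  if (n < 1L || n > length(spectrum$lambda)) stop("mode index out of range")
  dom <- spectrum$domain
  idx <- locate_compartment(dom, x)
  if (side == "left") {
    on_barrier <- x %in% dom$barriers[2:length(dom$D)]
    idx[on_barrier] <- idx[on_barrier] - 1L
    idx <- pmax.int(idx, 1L)
  }
  lam <- spectrum$lambda[n]
  A <- spectrum$A[n, idx]
  B <- spectrum$B[n, idx]
  if (lam == 0) return(A + 0 * x)
  alpha <- sqrt(lam / dom$D[idx])
  y <- x - dom$barriers[idx]
  A * cos(alpha * y) + B * sin(alpha * y)
}

# Mode values for all modes at a single position (one-sided).
# Returns a length-N vector.
all_modes_at <- function(spectrum, x, side = "right") {
  dom <- spectrum$domain
  i <- locate_compartment(dom, x)
  if (side == "left" && x %in% dom$barriers[2:length(dom$D)]) i <- i - 1L
  lam <- spectrum$lambda
  y <- x - dom$barriers[i]
  alpha <- sqrt(lam / dom$D[i])
  v <- spectrum$A[, i] * cos(alpha * y) + spectrum$B[, i] * sin(alpha * y)
  v[lam == 0] <- spectrum$A[lam == 0, i]
  v
}

# Mode evaluation matrix (N modes x length(x)).
mode_matrix <- function(spectrum, x) {
  dom <- spectrum$domain
  idx <- locate_compartment(dom, x)
  lam <- spectrum$lambda
  N <- length(lam)
  out <- matrix(0, N, length(x))
  for (i in unique(idx)) {
    sel <- idx == i
    y <- x[sel] - dom$barriers[i]
    alpha <- sqrt(lam / dom$D[i])            # length N
    out[, sel] <- spectrum$A[, i] * cos(outer(alpha, y)) +
      spectrum$B[, i] * sin(outer(alpha, y))
    if (lam[1L] == 0) out[1L, sel] <- spectrum$A[1L, i]
  }
  out
}

# Closed-form integral of each mode over [a, b] (inside the domain).
# Returns a length-N vector of integrals.
mode_integrals <- function(spectrum, a, b) {
  dom <- spectrum$domain
  if (a > b) stop("empty interval")
  lam <- spectrum$lambda
  N <- length(lam)
  out <- numeric(N)
  m <- length(dom$D)
  for (i in seq_len(m)) {
    lo <- max(a, dom$barriers[i])
    hi <- min(b, dom$barriers[i + 1L])
    if (hi <= lo) next
    y0 <- lo - dom$barriers[i]
    y1 <- hi - dom$barriers[i]
    alpha <- sqrt(lam / dom$D[i])
    Ai <- spectrum$A[, i]; Bi <- spectrum$B[, i]
    seg <- Ai * (sin(alpha * y1) - sin(alpha * y0)) / alpha +
      Bi * (cos(alpha * y0) - cos(alpha * y1)) / alpha
    zero <- lam == 0
    seg[zero] <- Ai[zero] * (y1 - y0)
    out <- out + seg
  }
  out
}

#' Diffusion propagator for a point (Dirac delta) initial condition
#'
#' Evaluates the truncated eigenmode expansion
#' `U(x, t) = sum_n exp(-lambda_n t) nu_n(x) nu_n(x0)`.
#' As `t -> infinity` only the constant mode survives and `U -> 1 / total
#' length`.
#'
#' @param spectrum a `pw_spectrum`.
#' @param x evaluation positions (um).
#' @param t time (ms), single value.
#' @param x0 source position (um).
#' @return a `pw_density_field`: list with `x`, `U` (1/um), `t`, `provenance`.
#' @export
propagator_delta <- function(spectrum, x, t, x0) {
  assert_spectrum(spectrum)
  if (t < 0) stop("t must be non-negative")
  w <- all_modes_at(spectrum, x0) * exp(-spectrum$lambda * t)
  U <- as.numeric(crossprod(mode_matrix(spectrum, x), w))
  structure(list(x = x, U = U, t = t, provenance = "eigen"),
            class = "pw_density_field")
}

#' Diffusion propagator for a uniform-interval initial condition
#'
#' By linearity, a uniform initial density on `[a, b]` is the normalised
#' superposition of point sources, giving
#' `U(x, t) = sum_n exp(-lambda_n t) nu_n(x) * (1/(b-a)) integral_a^b nu_n`.
#' The mode integrals are evaluated in closed form per compartment.
#'
#' @inheritParams propagator_delta
#' @param interval length-2 numeric `[a, b]` inside the domain; a degenerate
#'   interval delegates to [propagator_delta()].
#' @return a `pw_density_field`.
#' @export
propagator_uniform <- function(spectrum, x, t, interval) {
  assert_spectrum(spectrum)
  a <- interval[1L]; b <- interval[2L]
  dom <- spectrum$domain
  if (a > b) stop("interval must be ascending")
  if (a < dom$barriers[1L] || b > dom$barriers[length(dom$barriers)])
    stop("interval outside the domain")
  if (a == b) return(propagator_delta(spectrum, x, t, a))
  w <- mode_integrals(spectrum, a, b) / (b - a) * exp(-spectrum$lambda * t)
  U <- as.numeric(crossprod(mode_matrix(spectrum, x), w))
  structure(list(x = x, U = U, t = t, provenance = "eigen"),
            class = "pw_density_field")
}

#' @export
print.pw_density_field <- function(x, ...) {
  cat(sprintf("Density field (%s): %d points, t = %g ms, integral ~ %.6f\n",
              x$provenance, length(x$x), x$t,
              sum(diff(x$x) * (x$U[-1L] + x$U[-length(x$U)]) / 2)))
  invisible(x)
}

#' Steady-state (uniform) particle density of a sealed domain
#'
#' With impermeable ends the stationary density is uniform:
#' `1 / (b_m - b_0)`.
#'
#' @param domain a `pw_domain`.
#' @return density in 1/um.
#' @examples
#' steady_density(build_domain(c(20, 20), c(0.5, 2.5), 0.05))  # 0.025
#' @export
steady_density <- function(domain) {
  assert_domain(domain)
  1 / domain_length(domain)
}

# Interface-condition residuals of mode n at every internal barrier.
# Returns a matrix with columns flux_jump (D_i u'_L - D_j u'_R) and
# jump_residual (D_i u'_L - kappa (u_R - u_L)); used for self-consistency
# checks.
mode_interface_residuals <- function(spectrum, n) {
  dom <- spectrum$domain
  m <- length(dom$D)
  lam <- spectrum$lambda[n]
  out <- matrix(0, max(m - 1L, 0L), 2L,
                dimnames = list(NULL, c("flux_jump", "jump_residual")))
  for (i in seq_len(m - 1L)) {
    xb <- dom$barriers[i + 1L]
    alpha_i <- sqrt(lam / dom$D[i])
    Li <- dom$lengths[i]
    uL <- spectrum$A[n, i] * cos(alpha_i * Li) + spectrum$B[n, i] * sin(alpha_i * Li)
    dL <- alpha_i * (spectrum$B[n, i] * cos(alpha_i * Li) -
                       spectrum$A[n, i] * sin(alpha_i * Li))
    alpha_j <- sqrt(lam / dom$D[i + 1L])
    uR <- spectrum$A[n, i + 1L]
    dR <- alpha_j * spectrum$B[n, i + 1L]
    if (lam == 0) { dL <- 0; dR <- 0 }
    fluxL <- dom$D[i] * dL
    fluxR <- dom$D[i + 1L] * dR
    out[i, 1L] <- fluxL - fluxR
    out[i, 2L] <- fluxL - dom$kappa[i + 1L] * (uR - uL)
  }
  out
}
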