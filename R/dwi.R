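#' Wave number from b-value under the narrow pulse approximation
#'
#' With instantaneous diffusion-encoding gradients the b-value is
#' `b = q^2 Delta`, so `q = sqrt(b / Delta)`.
#'
#' @param b b-value (ms/um^2), non-negative.
#' @param Delta diffusion time (ms), positive.
#' @return wave number q (rad/um).
#' @export
q_from_b <- function(b, Delta) {
  if (any(b < 0)) stop("b must be non-negative")
  if (any(Delta <= 0)) stop("Delta must be positive")
  sqrt(b / Delta)
}

#' Random-walk diffusion-weighted signal (narrow pulse approximation)
#'
#' Signal magnitude from walker net displacements:
#' `S = |mean(exp(-i q (x(Delta) - x(0))))|`. Static spins give `S = 1`; free
#' Gaussian displacements give the classic `exp(-b D)` attenuation.
#'
#' @param x0 initial walker positions (um).
#' @param x final walker positions (um), same length.
#' @param q wave number (rad/um); vectorised.
#' @return signal attenuation(s) in `[0, 1]`.
#' @export
signal_rw <- function(x0, x, q) {
  if (length(x0) != length(x)) stop("x0 and x must have equal length")
  if (length(x0) == 0L) stop("empty position arrays")
  disp <- x - x0
  vapply(q, function(qq)
    sqrt(mean(cos(qq * disp))^2 + mean(sin(qq * disp))^2), 0)
}

#' Analytical diffusion-weighted signal from an eigen spectrum
#'
#' Narrow-pulse signal for uniform initial seeding across the domain:
#' `S = (1 / sum L_i) * sum_n exp(-lambda_n Delta) |integral nu_n(x) e^{iqx} dx|^2`.
#' The mode Fourier integrals are evaluated by trapezoidal quadrature on a
#' fine grid; the grid is refined (doubled) until the signal changes by less
#' than `tol`.
#'
#' @param spectrum a `pw_spectrum`.
#' @param q wave number (rad/um), scalar.
#' @param Delta diffusion time (ms).
#' @param grid_points initial number of quadrature points (default 2e4).
#' @param tol grid-convergence tolerance on S (default 1e-6; the quadrature
#'   error shrinks quadratically with the grid, so a passing check means the
#'   returned value is converged well beyond the Monte Carlo noise it is
#'   compared against).
#' @return signal attenuation in `[0, 1]`.
#' @export
signal_analytical <- function(spectrum, q, Delta, grid_points = 2e4, tol = 1e-6) {
  assert_spectrum(spectrum)
  if (Delta <= 0) stop("Delta must be positive")
  dom <- spectrum$domain
  if (max(spectrum$lambda) * Delta < 50)
    warning("spectrum may be truncated too early for Delta = ", Delta,
            " ms (max lambda_n * Delta = ", round(max(spectrum$lambda) * Delta, 2), ")")
  eval_S <- function(npts) {
    x <- seq(dom$barriers[1L], dom$barriers[length(dom$barriers)],
             length.out = npts)
    M <- mode_matrix(spectrum, x)          # N x npts
    wts <- rep(1, npts); wts[c(1L, npts)] <- 0.5
    h <- x[2L] - x[1L]
    re <- as.numeric(M %*% (cos(q * x) * wts)) * h
    im <- as.numeric(M %*% (sin(q * x) * wts)) * h
    sum(exp(-spectrum$lambda * Delta) * (re^2 + im^2)) / domain_length(dom)
  }
  S <- eval_S(grid_points)
  S2 <- eval_S(2L * grid_points)
  if (abs(S2 - S) > tol)
    warning("signal quadrature not converged: refine grid_points ",
            "(change on doubling = ", format(abs(S2 - S), digits = 3), ")")
  S2
}

#' Apparent diffusion coefficient from signal attenuation
#'
#' Inverts the mono-exponential relation `S/S0 = exp(-b ADC)` with `S0 = 1`
#' (signals here are magnitudes of unit-mean phasors).
#'
#' @param S signal attenuation in `(0, 1]`.
#' @param b b-value (ms/um^2), positive.
#' @return ADC (um^2/ms).
#' @export
adc_from_signal <- function(S, b) {
  if (any(S <= 0)) stop("S must be positive")
  if (any(b <= 0)) stop("b must be positive")
  -log(S) / b
}

#' Relative error between random-walk and analytical signals
#'
#' `|S_rw - S_ana| / S_ana`.
#'
#' @param S_rw random-walk signal.
#' @param S_ana analytical signal, positive.
#' @return non-negative fraction.
#' @export
signal_relative_error <- function(S_rw, S_ana) {
  if (any(S_ana <= 0)) stop("S_ana must be positive")
  abs(S_rw - S_ana) / S_ana
}
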