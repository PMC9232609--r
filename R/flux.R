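#' Analytical membrane flux from the eigen propagator
#'
#' Evaluates the net particle flux through an internal membrane,
#' `J(t) = kappa * (U(x_b^-, t) - U(x_b^+, t))`, with `U` from the eigenmode
#' expansion evaluated one-sidedly on each side of the barrier (each side in
#' its own compartment basis). The sign convention is `J > 0` for net flow in
#' `+x`, i.e. when the left concentration exceeds the right. The cumulative
#' flux is exact: each mode contributes
#' `kappa w_n (nu_n^- - nu_n^+) (1 - exp(-lambda_n t)) / lambda_n`.
#'
#' @param spectrum a `pw_spectrum`.
#' @param interface internal interface index (`1 .. m - 1`; interface `i`
#'   separates compartments `i` and `i + 1`).
#' @param times evaluation times (ms), ascending.
#' @param ic initial condition: `list(mode = "delta", x0 = )` or
#'   `list(mode = "uniform_interval", a = , b = )` or `"uniform_full"`
#'   (the stationary state, giving zero flux). Character shortcuts as in
#'   [sim_config()] are accepted.
#' @return a `pw_flux_series`: data fields `times`, `J` (1/ms), `cumulative`
#'   (fraction of walkers), plus `interface`, `source = "analytical"`, and a
#'   continuous-time flux function `Jfun` used by [peak_time()].
#' @export
analytical_flux <- function(spectrum, interface, times, ic) {
  assert_spectrum(spectrum)
  dom <- spectrum$domain
  m <- length(dom$D)
  if (interface < 1L || interface > m - 1L)
    stop("interface must be an internal interface index in 1..", m - 1L)
  kap <- dom$kappa[interface + 1L]
  ic <- parse_seeding(ic)
  w <- switch(ic$mode,
    delta = all_modes_at(spectrum, ic$x0),
    uniform_full = mode_integrals(spectrum, dom$barriers[1L],
                                  dom$barriers[m + 1L]) / domain_length(dom),
    uniform_interval = mode_integrals(spectrum, ic$a, ic$b) / (ic$b - ic$a),
    stop("unsupported initial condition: ", ic$mode)
  )
  xb <- dom$barriers[interface + 1L]
  dnu <- all_modes_at(spectrum, xb, side = "left") -
    all_modes_at(spectrum, xb, side = "right")
  lam <- spectrum$lambda
  coefs <- kap * w * dnu
  Jfun <- function(t) vapply(t, function(tt) sum(coefs * exp(-lam * tt)), 0)
  pos <- lam > 0
  cumfun <- function(t) vapply(
    t, function(tt) sum(coefs[pos] * (1 - exp(-lam[pos] * tt)) / lam[pos]), 0)
  structure(list(times = times, J = Jfun(times), cumulative = cumfun(times),
                 interface = interface, source = "analytical",
                 Jfun = Jfun, cumfun = cumfun, dt = NULL),
            class = "pw_flux_series")
}

#' Numerical membrane flux from a recorded run
#'
#' Converts the per-step directional crossing counts of a [run_simulation()]
#' run (with `record_flux = TRUE`) into the instantaneous net flux
#' `J_k = (n_LR - n_RL) / (Np * dt)` at `t_k = k dt`, and the cumulative flux
#' by exact step summation (`J_k * dt` accumulated), i.e. the net fraction of
#' walkers that has crossed the interface by each step.
#'
#' @param run a `pw_run` recorded with `record_flux = TRUE`.
#' @param interface internal interface index.
#' @return a `pw_flux_series` with `source = "numerical"`.
#' @export
numerical_flux <- function(run, interface) {
  if (!inherits(run, "pw_run")) stop("expected a 'pw_run'")
  if (is.null(run$cross_lr)) stop("run was not recorded with record_flux = TRUE")
  nifc <- ncol(run$cross_lr)
  if (interface < 1L || interface > nifc)
    stop("interface must be in 1..", nifc)
  Np <- run$config$Np
  dt <- run$config$dt
  net <- (run$cross_lr[, interface] - run$cross_rl[, interface]) / Np
  structure(list(times = run$times, J = net / dt, cumulative = cumsum(net),
                 interface = interface, source = "numerical",
                 Jfun = NULL, cumfun = NULL, dt = dt),
            class = "pw_flux_series")
}

#' @export
print.pw_flux_series <- function(x, ...) {
  cat(sprintf("%s flux series at interface %d: %d times in [%g, %g] ms, final cumulative %.5f\n",
              x$source, x$interface, length(x$times), min(x$times), max(x$times),
              x$cumulative[length(x$cumulative)]))
  invisible(x)
}

#' Block time-average of an instantaneous flux series
#'
#' Averages `J` over consecutive windows of fixed duration; used to compare
#' noisy per-step Monte Carlo flux with the analytical curve. A window equal
#' to the series step returns the series unchanged.
#'
#' @param series a `pw_flux_series` on a uniform time grid.
#' @param window window duration (ms); must be a multiple of the series step.
#' @return a `pw_flux_series` on the window-midpoint grid; `cumulative` holds
#'   the original cumulative flux at each window end.
#' @export
time_averaged_flux <- function(series, window) {
  if (!inherits(series, "pw_flux_series")) stop("expected a 'pw_flux_series'")
  dt <- if (!is.null(series$dt)) series$dt else unique(round(diff(series$times), 12))[1L]
  k <- window / dt
  if (abs(k - round(k)) > 1e-9)
    stop("window must be a whole multiple of the series time step")
  k <- as.integer(round(k))
  if (k == 1L) return(series)
  n <- length(series$times)
  nwin <- n %/% k
  if (nwin < 1L) stop("window longer than the series")
  idx <- seq_len(nwin * k)
  grp <- rep(seq_len(nwin), each = k)
  Jbar <- as.numeric(tapply(series$J[idx], grp, mean))
  tmid <- as.numeric(tapply(series$times[idx], grp, mean))
  structure(list(times = tmid, J = Jbar,
                 cumulative = series$cumulative[seq_len(nwin) * k],
                 interface = series$interface,
                 source = paste0(series$source, "_window_avg"),
                 Jfun = NULL, cumfun = NULL, dt = window),
            class = "pw_flux_series")
}

#' Signed relative error of the final cumulative flux
#'
#' `(J_num(T) - J_ana(T)) / J_ana(T)` at the common final time of the two
#' series (cumulative fluxes). Negative values mean the simulation
#' under-transports walkers across the membrane.
#'
#' @param numerical,analytical `pw_flux_series` objects ending at the same time.
#' @return signed fraction.
#' @export
endpoint_relative_error <- function(numerical, analytical) {
  tn <- numerical$times[length(numerical$times)]
  ta <- analytical$times[length(analytical$times)]
  if (abs(tn - ta) > 1e-9 * max(tn, ta, 1))
    stop("series end at different times (", tn, " vs ", ta, " ms)")
  Ja <- analytical$cumulative[length(analytical$cumulative)]
  if (Ja == 0) stop("analytical cumulative flux is zero at the endpoint")
  (numerical$cumulative[length(numerical$cumulative)] - Ja) / Ja
}

#' Global relative error between cumulative flux curves
#'
#' Time-integrated discrepancy over the whole simulation,
#' `eps = integral |J_num(t) - J_ana(t)| dt / integral J_ana(t) dt`
#' (cumulative fluxes, trapezoidal on the numerical step grid): the area
#' between the numerical and analytical cumulative-flux curves, normalised by
#' the area under the analytical one.
#'
#' @param numerical a numerical `pw_flux_series`.
#' @param analytical an analytical `pw_flux_series`; its continuous cumulative
#'   flux is evaluated at the numerical step times.
#' @return non-negative fraction.
#' @export
global_error <- function(numerical, analytical) {
  tt <- numerical$times
  ca <- if (!is.null(analytical$cumfun)) analytical$cumfun(tt) else {
    if (length(analytical$times) != length(tt) ||
        max(abs(analytical$times - tt)) > 1e-9)
      stop("analytical series is not on the numerical time grid")
    analytical$cumulative
  }
  trap <- function(y) sum(diff(tt) * (y[-1L] + y[-length(y)]) / 2)
  denom <- trap(ca)
  if (denom == 0) stop("analytical cumulative flux integrates to zero")
  trap(abs(numerical$cumulative - ca)) / denom
}

#' Time of the flux peak
#'
#' Argmax of the instantaneous flux. For an analytical series the discrete
#' argmax is refined by maximising the continuous flux function locally
#' (tolerance 0.01 ms); for a discrete series the earliest maximiser is
#' returned.
#'
#' @param series a `pw_flux_series`.
#' @return peak time (ms).
#' @export
peak_time <- function(series) {
  if (!inherits(series, "pw_flux_series")) stop("expected a 'pw_flux_series'")
  if (all(series$J == 0)) stop("flux is identically zero; peak undefined")
  k <- which.max(series$J)
  if (is.null(series$Jfun)) return(series$times[k])
  lo <- series$times[max(1L, k - 1L)]
  hi <- series$times[min(length(series$times), k + 1L)]
  if (lo == hi) return(lo)
  stats::optimize(series$Jfun, c(lo, hi), maximum = TRUE, tol = 0.01)$maximum
}
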