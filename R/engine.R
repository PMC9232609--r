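#' Reference-model membrane transit probability
#'
#' The classical transit rule for a walker at distance `dx_i` from a membrane
#' of permeability `kappa`, approaching from a compartment with diffusivity
#' `D_i`:
#' `p = 2 kappa dx_i / (D_i + 2 kappa dx_i)`.
#' The probability depends only on the incident side, which is why this model
#' mis-handles steps in diffusivity unless the time step (hence `dx_i`) is
#' kept very small (see [max_timestep_reference()]).
#'
#' @param D_i incident-side diffusivity (um^2/ms), positive.
#' @param kappa membrane permeability (um/ms), non-negative.
#' @param dx_i distance from the walker to the barrier (um), non-negative.
#' @return transit probability in `[0, 1)`.
#' @export
transit_probability_reference <- function(D_i, kappa, dx_i) {
  if (any(D_i <= 0)) stop("D_i must be positive")
  if (any(kappa < 0)) stop("kappa must be non-negative")
  if (any(dx_i < 0)) stop("dx_i must be non-negative")
  2 * kappa * dx_i / (D_i + 2 * kappa * dx_i)
}

#' Hybrid membrane transit probability
#'
#' Treats the membrane and the diffusivity step as two interactions separated
#' by an infinitesimal gap, with the membrane sitting on the low-diffusivity
#' side: the transit probability factorises as `p = p_b * p_d`, where
#' `p_d = min(1, sqrt(D_j / D_i))` is the diffusivity-step acceptance and
#' `p_b` is the reference membrane probability evaluated *in the
#' low-diffusivity medium*, with the walker's distance to the barrier mapped
#' into that medium by the step rescaling:
#' `p_b = 2 kappa dx' / (min(D_i, D_j) + 2 kappa dx')` with
#' `dx' = dx_i * min(1, sqrt(D_j / D_i))`.
#'
#' For `D_i <= D_j` this reduces exactly to
#' [transit_probability_reference()] (`p_d = 1`, `dx' = dx_i`). For
#' `D_i > D_j` the rule both penalises the crossing by `p_d` (restoring the
#' interface reflection condition in the `kappa -> infinity` limit) and
#' evaluates the membrane factor consistently on the membrane's side of the
#' gap; at equilibrium the directional crossing rates then balance at every
#' order of the step length, which is what preserves a uniform steady state
#' at large time steps.
#'
#' @inheritParams transit_probability_reference
#' @param D_j destination-side diffusivity (um^2/ms), positive.
#' @return transit probability in `[0, 1)`.
#' @export
transit_probability_hybrid <- function(D_i, D_j, kappa, dx_i) {
  if (any(D_j <= 0)) stop("D_j must be positive")
  if (any(D_i <= 0)) stop("D_i must be positive")
  if (any(kappa < 0)) stop("kappa must be non-negative")
  if (any(dx_i < 0)) stop("dx_i must be non-negative")
  p_d <- pmin(1, sqrt(D_j / D_i))
  dxe <- dx_i * p_d
  D_low <- pmin(D_i, D_j)
  p_d * 2 * kappa * dxe / (D_low + 2 * kappa * dxe)
}

#' Simulation configuration
#'
#' @param dt time step (ms); must not exceed [max_timestep_domain()] of the
#'   domain it is run on (at most one membrane interaction per step).
#' @param T_total total simulated time (ms); the run takes `ceiling(T/dt)`
#'   full steps and the reported final time is `steps * dt`.
#' @param Np number of walkers.
#' @param seeding one of `"uniform_full"`, `list(mode = "delta", x0 = )`,
#'   or `list(mode = "uniform_interval", a = , b = )`. The character
#'   shortcuts `"delta:24.75"` and `"interval:6,14"` are also accepted.
#' @param model membrane transit model, `"hybrid"` or `"reference"`.
#' @param seed optional integer; when given, `set.seed(seed)` is called at the
#'   start of the run so results are bit-reproducible.
#' @param record_flux record per-step directional crossing counts at every
#'   internal interface (needed for [numerical_flux()]).
#' @param record_counts record per-step compartment occupancy counts.
#' @param snapshot_times times (ms) at which to store full position snapshots;
#'   rounded to the nearest step.
#' @return an object of class `pw_sim_config`.
#' @export
sim_config <- function(dt, T_total, Np, seeding = "uniform_full",
                       model = c("hybrid", "reference"), seed = NULL,
                       record_flux = FALSE, record_counts = FALSE,
                       snapshot_times = numeric(0)) {
  model <- match.arg(model)
  if (dt <= 0) stop("dt must be positive")
  if (T_total < dt) stop("T_total must be at least one step")
  if (Np < 1) stop("Np must be at least 1")
  seeding <- parse_seeding(seeding)
  structure(list(dt = dt, T_total = T_total, Np = as.integer(Np),
                 seeding = seeding, model = model, seed = seed,
                 record_flux = record_flux, record_counts = record_counts,
                 snapshot_times = snapshot_times),
            class = "pw_sim_config")
}

parse_seeding <- function(seeding) {
  if (is.list(seeding)) {
    if (is.null(seeding$mode)) stop("seeding list needs a 'mode' field")
    return(seeding)
  }
  if (!is.character(seeding) || length(seeding) != 1L)
    stop("seeding must be a mode string or a list")
  if (seeding == "uniform_full") return(list(mode = "uniform_full"))
  if (startsWith(seeding, "delta:")) {
    return(list(mode = "delta", x0 = as.numeric(sub("^delta:", "", seeding))))
  }
  if (startsWith(seeding, "interval:")) {
    ab <- as.numeric(strsplit(sub("^interval:", "", seeding), ",")[[1L]])
    if (length(ab) != 2L || anyNA(ab)) stop("interval seeding needs 'interval:a,b'")
    return(list(mode = "uniform_interval", a = ab[1L], b = ab[2L]))
  }
  stop("unknown seeding specification: ", seeding)
}

#' Draw initial walker positions
#'
#' @param seeding a seeding specification (see [sim_config()]).
#' @param Np number of walkers.
#' @param domain a `pw_domain`.
#' @return numeric vector of positions (um). Uses the current RNG state.
#' @export
seed_walkers <- function(seeding, Np, domain) {
  assert_domain(domain)
  seeding <- parse_seeding(seeding)
  b <- domain$barriers
  lo <- b[1L]; hi <- b[length(b)]
  switch(seeding$mode,
    delta = {
      if (seeding$x0 < lo || seeding$x0 > hi) stop("x0 outside the domain")
      rep(seeding$x0, Np)
    },
    uniform_full = stats::runif(Np, lo, hi),
    uniform_interval = {
      if (seeding$a < lo || seeding$b > hi || seeding$a > seeding$b)
        stop("seeding interval outside the domain")
      stats::runif(Np, seeding$a, seeding$b)
    },
    stop("unknown seeding mode: ", seeding$mode)
  )
}

#' Run a random-walk simulation
#'
#' Advances `Np` independent walkers for `ceiling(T_total / dt)` steps with
#' the chosen membrane transit model. All randomness flows through R's RNG,
#' so a fixed `seed` makes the run bit-reproducible; with uniform diffusivity
#' the reference and hybrid models consume identical draws and produce
#' bit-identical trajectories.
#'
#' @param domain a `pw_domain`.
#' @param config a [sim_config()].
#' @return an object of class `pw_run`: initial and final positions, final
#'   compartments, step times, per-step crossing counts (`cross_lr`,
#'   `cross_rl`, steps x internal interfaces, when `record_flux`), per-step
#'   compartment occupancy (`counts`, when `record_counts`), position
#'   snapshots, and the config/domain used.
#' @export
run_simulation <- function(domain, config) {
  assert_domain(domain)
  if (!inherits(config, "pw_sim_config")) stop("expected a 'pw_sim_config'")
  dt_max <- max_timestep_domain(domain)
  if (config$dt > dt_max)
    stop(sprintf("dt = %g ms exceeds the domain limit dt_max = %g ms", config$dt, dt_max))
  if (!is.null(config$seed)) set.seed(config$seed)
  nsteps <- as.integer(ceiling(config$T_total / config$dt - 1e-9))
  x0 <- seed_walkers(config$seeding, config$Np, domain)
  comp0 <- locate_compartment(domain, x0) - 1L
  snap_steps <- sort(unique(pmin(pmax(as.integer(round(
    config$snapshot_times / config$dt)), 1L), nsteps)))
  res <- .rw_simulate(domain$barriers, domain$D, domain$kappa,
                      x0, comp0, config$dt, nsteps,
                      if (config$model == "hybrid") 1L else 0L,
                      config$record_flux, config$record_counts,
                      if (length(config$snapshot_times)) snap_steps else integer(0))
  structure(list(
    x0 = x0, x = res$x, comp = res$comp + 1L,
    times = seq_len(nsteps) * config$dt,
    cross_lr = if (config$record_flux) res$cross_lr else NULL,
    cross_rl = if (config$record_flux) res$cross_rl else NULL,
    counts = if (config$record_counts) res$counts else NULL,
    snapshots = if (length(config$snapshot_times))
      stats::setNames(res$snapshots, snap_steps * config$dt) else NULL,
    domain = domain, config = config
  ), class = "pw_run")
}

#' @export
print.pw_run <- function(x, ...) {
  cat(sprintf("Random walk run: %d walkers, %d steps of %g ms (%s model)\n",
              x$config$Np, length(x$times), x$config$dt, x$config$model))
  invisible(x)
}

#' Density-normalised position histogram
#'
#' Bins tile the domain; each bin's density is `count / (Np * bin_width)`, so
#' the densities integrate to 1 over the domain.
#'
#' @param positions numeric vector of walker positions (um).
#' @param bin_width bin width (um).
#' @param domain a `pw_domain`.
#' @return a data.frame with columns `center`, `width`, `count`, `density`.
#' @export
density_histogram <- function(positions, bin_width, domain) {
  assert_domain(domain)
  if (bin_width <= 0) stop("bin_width must be positive")
  b <- domain$barriers
  lo <- b[1L]; hi <- b[length(b)]
  nb <- max(1L, as.integer(ceiling((hi - lo) / bin_width - 1e-9)))
  edges <- lo + bin_width * seq.int(0L, nb)
  edges[nb + 1L] <- hi   # last bin absorbs any remainder
  idx <- findInterval(positions, edges, rightmost.closed = TRUE)
  idx <- pmin.int(pmax.int(idx, 1L), nb)
  count <- tabulate(idx, nbins = nb)
  width <- diff(edges)
  data.frame(center = (edges[-1L] + edges[-(nb + 1L)]) / 2,
             width = width, count = count,
             density = count / (length(positions) * width))
}

#' Per-compartment walker fractions of a run
#'
#' Fraction of walkers in each compartment at the final step, or at every
#' recorded step when the run stored occupancy counts.
#'
#' @param run a `pw_run`.
#' @param at `"final"` or `"all"` (requires `record_counts`).
#' @return numeric vector of fractions (at = "final"), or a steps x m matrix.
#' @export
compartment_fractions <- function(run, at = c("final", "all")) {
  at <- match.arg(at)
  m <- length(run$domain$D)
  if (at == "final") {
    tabulate(run$comp, nbins = m) / length(run$comp)
  } else {
    if (is.null(run$counts)) stop("run was not recorded with record_counts")
    run$counts / length(run$comp)
  }
}
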