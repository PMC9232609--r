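#' Write a domain to a YAML or JSON file
#'
#' The file stores `lengths`, `diffusivities`, `permeabilities` (internal
#' interfaces only), `origin`, and optional `labels`; [read_domain()]
#' round-trips it exactly.
#'
#' @param domain a `pw_domain`.
#' @param path output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_domain <- function(domain, path) {
  assert_domain(domain)
  m <- length(domain$D)
  obj <- list(lengths = domain$lengths,
              diffusivities = domain$D,
              permeabilities = if (m > 1L) domain$kappa[2:m] else numeric(0),
              origin = domain$barriers[1L])
  if (!is.null(domain$labels)) obj$labels <- domain$labels
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path, precision = 17L)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE, pretty = TRUE)
  } else stop("unsupported extension (use .yaml, .yml or .json): ", path)
  invisible(path)
}

#' Read a domain from a YAML or JSON file
#'
#' Accepts either explicit `diffusivities`, or `labels` plus `D_ICS`/`D_ECS`
#' values. Unknown keys are rejected.
#'
#' @param path file written by [write_domain()] or hand-authored with the
#'   same schema.
#' @return a `pw_domain`.
#' @export
read_domain <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported extension (use .yaml, .yml or .json): ", path)
  known <- c("lengths", "diffusivities", "permeabilities", "origin", "labels",
             "D_ICS", "D_ECS")
  extra <- setdiff(names(obj), known)
  if (length(extra)) stop("unknown key(s) in domain file: ", paste(extra, collapse = ", "))
  if (is.null(obj$lengths)) stop("domain file is missing 'lengths'")
  if (is.null(obj$diffusivities)) {
    if (is.null(obj$labels) || is.null(obj$D_ICS) || is.null(obj$D_ECS))
      stop("domain file is missing 'diffusivities' (or 'labels' + 'D_ICS'/'D_ECS')")
    obj$diffusivities <- ifelse(obj$labels == "ICS", obj$D_ICS, obj$D_ECS)
  }
  if (is.null(obj$permeabilities)) {
    if (length(obj$lengths) > 1L) stop("domain file is missing 'permeabilities'")
    obj$permeabilities <- numeric(0)
  }
  build_domain(unlist(obj$lengths), unlist(obj$diffusivities),
               unlist(obj$permeabilities),
               origin = if (is.null(obj$origin)) 0 else obj$origin,
               labels = obj$labels)
}

#' Run-reproducibility manifest
#'
#' A JSON-serialisable snapshot of a run's configuration: domain, simulation
#' settings and seed. Re-running [run_simulation()] from a manifest is
#' bit-identical.
#'
#' @param run a `pw_run`.
#' @param path optional path to also write the manifest as JSON.
#' @return the manifest list, invisibly when `path` is given.
#' @export
run_manifest <- function(run, path = NULL) {
  if (!inherits(run, "pw_run")) stop("expected a 'pw_run'")
  dom <- run$domain
  cfg <- run$config
  man <- list(
    package = "permwalk",
    version = as.character(utils::packageVersion("permwalk")),
    domain = list(lengths = dom$lengths, diffusivities = dom$D,
                  permeabilities = dom$kappa[2:max(length(dom$D), 2L)][seq_len(length(dom$D) - 1L)],
                  origin = dom$barriers[1L], labels = dom$labels),
    config = list(dt = cfg$dt, T_total = cfg$T_total, Np = cfg$Np,
                  seeding = cfg$seeding, model = cfg$model, seed = cfg$seed,
                  record_flux = cfg$record_flux, record_counts = cfg$record_counts)
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(man))
  }
  man
}

#' Re-create a run from a manifest
#'
#' @param manifest list as returned by [run_manifest()], or a path to its
#'   JSON file.
#' @return a `pw_run`.
#' @export
run_from_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  labels <- manifest$domain$labels
  if (length(labels) == 0L) labels <- NULL
  dom <- build_domain(manifest$domain$lengths, manifest$domain$diffusivities,
                      manifest$domain$permeabilities,
                      origin = manifest$domain$origin %||% 0,
                      labels = labels)
  cfg <- manifest$config
  seeding <- cfg$seeding
  if (is.list(seeding)) seeding <- lapply(seeding, function(v) if (is.list(v)) unlist(v) else v)
  run_simulation(dom, sim_config(cfg$dt, cfg$T_total, cfg$Np, seeding = seeding,
                                 model = cfg$model, seed = cfg$seed,
                                 record_flux = isTRUE(cfg$record_flux),
                                 record_counts = isTRUE(cfg$record_counts)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Named benchmark experiments
#'
#' Drivers that run the package's standard validation experiments on the
#' two-compartment benchmark (two 20 um compartments, `D_L = 0.5`,
#' `D_R = 2.5` um^2/ms, internal `kappa = 0.05` um/ms) or a synthesised
#' histology domain, and return tidy result tables.
#'
#' * `"steady_state"`: uniform seeding; per-model, per-time-step
#'   left-compartment excess over the uniform steady state at `T`.
#' * `"step_size"`: point seeding at the centre of the left compartment;
#'   per-model, per-time-step endpoint relative error and global error of the
#'   cumulative membrane flux against the eigenmode solution, plus the
#'   analytical peak time.
#' * `"perm_sweep"`: partial uniform seeding `x0` in `[6, 14]` um; grid over
#'   time steps, diffusivity ratios `D_R / D_L` (with `D_L = 2`), two
#'   permeabilities and both models; global error per cell.
#' * `"histology"`: synthesised histology domain; steady-state check and
#'   transient density snapshots against the eigen propagator.
#' * `"dwi_sweep"`: histology domain; random-walk vs analytical narrow-pulse
#'   signal and ADC across a permeability sweep.
#'
#' @param name experiment name.
#' @param Np walkers per run (default 1e5; the headline experiments in the
#'   package documentation use 1e6).
#' @param seed base seed.
#' @param dts,ratios,kappas,models optional overrides of the experiment grid.
#' @param T_total simulated time (ms).
#' @return a data.frame of per-cell metrics.
#' @export
reproduce_experiment <- function(name = c("steady_state", "step_size", "perm_sweep",
                                          "histology", "dwi_sweep"),
                                 Np = 1e5, seed = 1, dts = NULL, ratios = NULL,
                                 kappas = NULL, models = c("reference", "hybrid"),
                                 T_total = 1000) {
  name <- match.arg(name)
  switch(name,
    steady_state = {
      dom <- build_domain(c(20, 20), c(0.5, 2.5), 0.05)
      dts <- dts %||% c(20, 10, 5, 2, 0.5, 0.05)
      grid <- expand.grid(model = models, dt = dts, stringsAsFactors = FALSE)
      grid$excess_left <- mapply(function(model, dt) {
        run <- run_simulation(dom, sim_config(dt, T_total, Np, "uniform_full",
                                              model = model, seed = seed))
        f <- compartment_fractions(run)
        f[1L] / 0.5 - 1
      }, grid$model, grid$dt)
      grid
    },
    step_size = {
      dom <- build_domain(c(20, 20), c(0.5, 2.5), 0.05)
      sp <- find_eigenvalues(dom, lambda_max = 200, scan_points = 5e4)
      dts <- dts %||% c(20, 0.5)
      ic <- "interval:0,20"
      grid <- expand.grid(model = models, dt = dts, stringsAsFactors = FALSE)
      res <- mapply(function(model, dt) {
        run <- run_simulation(dom, sim_config(dt, T_total, Np, ic, model = model,
                                              seed = seed, record_flux = TRUE))
        fn <- numerical_flux(run, 1L)
        fa <- analytical_flux(sp, 1L, fn$times, ic)
        c(endpoint_relative_error(fn, fa), global_error(fn, fa))
      }, grid$model, grid$dt)
      grid$endpoint_error <- res[1L, ]
      grid$global_error <- res[2L, ]
      # the peak of the transient flux is only interior for a point release;
      # the canonical peak-time diagnostic uses a delta at the centre of the
      # left compartment
      attr(grid, "peak_time_ms") <- peak_time(
        analytical_flux(sp, 1L, seq(1, T_total), "delta:10"))
      grid
    },
    perm_sweep = {
      dts <- dts %||% c(40, 8, 4, 2, 0.5, 0.1, 0.05)
      ratios <- ratios %||% c(2.5, 1.8, 1.6, 1, 0.4, 0.2, 0.1, 0.05)
      kappas <- kappas %||% c(0.05, 0.5)
      grid <- expand.grid(model = models, dt = dts, ratio = ratios,
                          kappa = kappas, stringsAsFactors = FALSE)
      grid$global_error <- mapply(function(model, dt, ratio, kappa) {
        dom <- build_domain(c(20, 20), c(2, 2 * ratio), kappa)
        sp <- find_eigenvalues(dom, lambda_max = max(200, 60 / dt),
                               scan_points = 2e4)
        run <- run_simulation(dom, sim_config(dt, T_total, Np, "interval:6,14",
                                              model = model, seed = seed,
                                              record_flux = TRUE))
        fn <- numerical_flux(run, 1L)
        fa <- analytical_flux(sp, 1L, fn$times, "interval:6,14")
        global_error(fn, fa)
      }, grid$model, grid$dt, grid$ratio, grid$kappa)
      grid
    },
    histology = {
      set.seed(seed)
      dom <- synthesize_histology_domain()
      dt <- min(dts %||% 1.5, 0.9 * max_timestep_domain(dom))
      sp <- find_eigenvalues(dom, lambda_max = 500, n_max = 1000, scan_points = 1e5)
      x0 <- sum(range(dom$barriers)) / 2
      grid <- expand.grid(model = models, stringsAsFactors = FALSE)
      rho <- steady_density(dom)
      res <- mapply(function(model) {
        run <- run_simulation(dom, sim_config(dt, T_total, Np, "uniform_full",
                                              model = model, seed = seed + 1))
        h <- density_histogram(run$x, 0.5, dom)
        max(abs(h$density - rho)) / rho
      }, grid$model)
      grid$max_density_dev <- res
      attr(grid, "domain") <- dom
      attr(grid, "spectrum") <- sp
      attr(grid, "x0") <- x0
      grid
    },
    dwi_sweep = {
      set.seed(seed)
      dom <- synthesize_histology_domain(kappa = 0.05)
      kappas <- kappas %||% seq(0, 1, length.out = 11)
      dt <- dts %||% 1.5
      b <- 1; Delta <- T_total
      grid <- expand.grid(model = models, kappa = kappas, stringsAsFactors = FALSE)
      res <- mapply(function(model, kappa) {
        domk <- build_domain(dom$lengths, dom$D,
                             rep(kappa, length(dom$lengths) - 1L),
                             labels = dom$labels)
        dtk <- min(dt, 0.9 * max_timestep_domain(domk))
        spk <- find_eigenvalues(domk, lambda_max = 500, n_max = 1000,
                                scan_points = 5e4)
        q <- q_from_b(b, Delta)
        run <- run_simulation(domk, sim_config(dtk, Delta, Np, "uniform_full",
                                               model = model, seed = seed + 1))
        S_rw <- signal_rw(run$x0, run$x, q)
        S_ana <- signal_analytical(spk, q, Delta)
        c(S_rw, S_ana, adc_from_signal(S_rw, b), adc_from_signal(S_ana, b),
          signal_relative_error(S_rw, S_ana))
      }, grid$model, grid$kappa)
      grid$S_rw <- res[1L, ]; grid$S_ana <- res[2L, ]
      grid$ADC_rw <- res[3L, ]; grid$ADC_ana <- res[4L, ]
      grid$signal_rel_error <- res[5L, ]
      grid
    }
  )
}
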