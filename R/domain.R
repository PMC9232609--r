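#' Build a 1D layered domain
#'
#' A domain is an ordered array of `m` compartments, each with a constant
#' diffusivity, separated by semi-permeable membranes. Compartment `i` spans
#' `[b[i], b[i+1]]` of the barrier vector `b`; the membrane between
#' compartments `i` and `i+1` has permeability `kappa[i+1]` (distance/time).
#' The domain ends are always impermeable (`kappa[1] = kappa[m+1] = 0`), so
#' walkers are conserved.
#'
#' @param lengths numeric vector of compartment lengths (um), all positive.
#' @param diffusivities numeric vector of per-compartment diffusion
#'   coefficients (um^2/ms), same length as `lengths`, all positive.
#' @param internal_permeabilities numeric vector of membrane permeabilities
#'   (um/ms) for the `m - 1` internal interfaces, all non-negative. May be
#'   empty for a single compartment.
#' @param origin position of the left end `b[1]` (um). Default 0.
#' @param labels optional character vector of per-compartment tags, e.g.
#'   `"ICS"` / `"ECS"`.
#'
#' @return An object of class `pw_domain` with fields `barriers` (length
#'   `m + 1`), `D` (length `m`), `kappa` (length `m + 1`, ends zero),
#'   `lengths`, and `labels`.
#' @examples
#' dom <- build_domain(c(20, 20), c(0.5, 2.5), 0.05)
#' dom$barriers   # 0 20 40
#' dom$kappa      # 0 0.05 0
#' @export
build_domain <- function(lengths, diffusivities, internal_permeabilities = numeric(0),
                         origin = 0, labels = NULL) {
  lengths <- as.numeric(lengths)
  diffusivities <- as.numeric(diffusivities)
  internal_permeabilities <- as.numeric(internal_permeabilities)
  m <- length(lengths)
  if (m < 1L) stop("domain needs at least one compartment")
  if (length(diffusivities) != m)
    stop("need one diffusivity per compartment (", m, "), got ", length(diffusivities))
  if (length(internal_permeabilities) != m - 1L)
    stop("need ", m - 1L, " internal permeabilities, got ", length(internal_permeabilities))
  bad <- which(!is.finite(lengths) | lengths <= 0)
  if (length(bad)) stop("non-positive compartment length at index ", bad[1L])
  bad <- which(!is.finite(diffusivities) | diffusivities <= 0)
  if (length(bad)) stop("non-positive diffusivity at index ", bad[1L])
  bad <- which(!is.finite(internal_permeabilities) | internal_permeabilities < 0)
  if (length(bad)) stop("negative permeability at internal interface ", bad[1L])
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != m) stop("need one label per compartment")
  }
  structure(
    list(
      barriers = origin + c(0, cumsum(lengths)),
      D = diffusivities,
      kappa = c(0, internal_permeabilities, 0),
      lengths = lengths,
      labels = labels
    ),
    class = "pw_domain"
  )
}

#' @export
print.pw_domain <- function(x, ...) {
  m <- length(x$D)
  cat("1D layered domain:", m, "compartment(s),",
      sprintf("[%g, %g] um\n", x$barriers[1L], x$barriers[m + 1L]))
  df <- data.frame(
    length_um = x$lengths,
    D_um2_ms = x$D,
    kappa_right = x$kappa[-1L]
  )
  if (!is.null(x$labels)) df$label <- x$labels
  print(df, row.names = TRUE)
  invisible(x)
}

assert_domain <- function(domain) {
  if (!inherits(domain, "pw_domain")) stop("expected a 'pw_domain' object")
  invisible(domain)
}

domain_length <- function(domain) {
  m <- length(domain$D)
  domain$barriers[m + 1L] - domain$barriers[1L]
}

#' Locate the compartment containing a position
#'
#' Stateless point query: compartments are half-open `[b[i], b[i+1])` with
#' right closure at the last barrier, so a position exactly on an internal
#' barrier maps to the compartment on its right. (The walk engine instead
#' tracks each walker's current compartment explicitly, which resolves
#' barrier-exact positions by history.)
#'
#' @param domain a `pw_domain`.
#' @param x numeric vector of positions (um), all inside the domain.
#' @return integer vector of compartment indices in `1..m`.
#' @export
locate_compartment <- function(domain, x) {
  assert_domain(domain)
  b <- domain$barriers
  m <- length(domain$D)
  if (any(x < b[1L] | x > b[m + 1L]))
    stop("position outside the domain [", b[1L], ", ", b[m + 1L], "]")
  idx <- findInterval(x, b, rightmost.closed = TRUE)
  pmin.int(pmax.int(idx, 1L), m)
}

#' Largest stable time step for a domain
#'
#' The walk engine permits at most one membrane interaction per step, which
#' requires that a single step cannot span a full compartment:
#' `dt_max = min_i L_i^2 / (2 D_i)`.
#'
#' @param domain a `pw_domain`.
#' @return time step bound in ms.
#' @examples
#' max_timestep_domain(build_domain(c(20, 20), c(0.5, 2.5), 0.05))  # 80
#' @export
max_timestep_domain <- function(domain) {
  assert_domain(domain)
  min(domain$lengths^2 / (2 * domain$D))
}

#' Time-step bound for the reference transit model
#'
#' The reference model is only accurate when its transit probability stays
#' small; its authors recommend capping the probability evaluated at a full
#' step `dx = sqrt(2 D dt)` at `p_max = 0.01`. Solving
#' `2 kappa dx / (D + 2 kappa dx) = p_max` for `dt` gives the closed form
#' `dt = p_max^2 D / (8 kappa^2 (1 - p_max)^2)`.
#'
#' @param D incident-side diffusivity (um^2/ms).
#' @param kappa membrane permeability (um/ms). `kappa = 0` gives `Inf`.
#' @param p_max maximum admissible transit probability (default 0.01).
#' @return time step bound in ms (`Inf` for an impermeable membrane).
#' @examples
#' max_timestep_reference(0.5, 0.05)  # ~0.00255 ms
#' @export
max_timestep_reference <- function(D, kappa, p_max = 0.01) {
  if (any(D <= 0)) stop("diffusivity must be positive")
  if (any(kappa < 0)) stop("permeability must be non-negative")
  if (any(p_max <= 0 | p_max >= 1)) stop("p_max must be in (0, 1)")
  ifelse(kappa == 0, Inf, p_max^2 * D / (8 * kappa^2 * (1 - p_max)^2))
}

#' Reference-model time-step bound for a whole domain
#'
#' Minimum of [max_timestep_reference()] over every (compartment,
#' adjacent-internal-interface) pair.
#'
#' @inheritParams max_timestep_domain
#' @inheritParams max_timestep_reference
#' @return time step bound in ms.
#' @export
max_timestep_reference_domain <- function(domain, p_max = 0.01) {
  assert_domain(domain)
  m <- length(domain$D)
  if (m == 1L) return(Inf)
  dt <- Inf
  for (i in seq_len(m)) {
    for (k in c(i, i + 1L)) {          # left and right interface of compartment i
      if (k >= 2L && k <= m) {         # internal interfaces only
        dt <- min(dt, max_timestep_reference(domain$D[i], domain$kappa[k], p_max))
      }
    }
  }
  dt
}

#' Cell cross-sectional area to diameter
#'
#' Assumes circular cell cross-sections: `d = 2 sqrt(A / pi)`.
#'
#' @param area cross-sectional area (um^2), positive.
#' @return diameter (um).
#' @examples
#' area_to_diameter(120)  # ~12.4 um
#' @export
area_to_diameter <- function(area) {
  if (any(!is.finite(area) | area <= 0)) stop("area must be positive")
  2 * sqrt(area / pi)
}

#' Summary statistics describing a histology-derived tissue section
#'
#' Container for the cell-size statistics used to synthesise 1D
#' intra-/extra-cellular domains: cell cross-sectional areas follow a normal
#' distribution truncated to `mean +/- 2 sd`, and extracellular gap widths are
#' uniform on `ecs_range`. The defaults describe cardiomyocytes in sections of
#' swine myocardium cut perpendicular to the cell long axis.
#'
#' @param mean_area mean cell cross-sectional area (um^2).
#' @param sd_area standard deviation of the cell area (um^2).
#' @param ecs_range length-2 numeric, uniform range of extracellular widths (um).
#' @param total_length target total domain length (um).
#' @return an object of class `pw_histology_stats`.
#' @export
histology_stats <- function(mean_area = 120, sd_area = 40,
                            ecs_range = c(3, 5), total_length = 49.5) {
  if (mean_area <= 0) stop("mean_area must be positive")
  if (sd_area < 0) stop("sd_area must be non-negative")
  if (length(ecs_range) != 2L || ecs_range[1L] > ecs_range[2L])
    stop("ecs_range must be an ascending length-2 interval")
  if (total_length <= 0) stop("total_length must be positive")
  structure(
    list(mean_area = mean_area, sd_area = sd_area,
         ecs_range = as.numeric(ecs_range), total_length = total_length),
    class = "pw_histology_stats"
  )
}

#' Sample intracellular compartment diameters
#'
#' Draws cell cross-sectional areas from a normal distribution truncated (by
#' rejection) to `mean_area +/- 2 sd_area` and converts them to diameters
#' assuming circular cross-sections. The truncation bound is also clipped at
#' zero so areas are always positive.
#'
#' @param n number of draws.
#' @param stats a [histology_stats()] object.
#' @return numeric vector of diameters (um).
#' @export
sample_ics_diameters <- function(n, stats) {
  if (!inherits(stats, "pw_histology_stats")) stop("expected 'pw_histology_stats'")
  lo <- max(stats$mean_area - 2 * stats$sd_area, .Machine$double.eps)
  hi <- stats$mean_area + 2 * stats$sd_area
  if (stats$sd_area == 0) return(rep(area_to_diameter(stats$mean_area), n))
  areas <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), stats$mean_area, stats$sd_area)
    ok <- draw >= lo & draw <= hi
    areas[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  area_to_diameter(areas)
}

#' Synthesise a histology-based 1D domain
#'
#' Builds an alternating intra-/extra-cellular domain from cell-size summary
#' statistics: intracellular lengths are diameters of truncated-normal areas,
#' extracellular lengths are uniform draws, and drawing alternates (starting
#' from `first`) until the cumulative length would exceed
#' `stats$total_length`; the final compartment is truncated so the total
#' length is met exactly. Intracellular compartments receive `D_ics`,
#' extracellular ones `D_ecs`, and every internal membrane the same `kappa`.
#'
#' Uses the current RNG state; call `set.seed()` beforehand for a
#' reproducible realisation.
#'
#' @param stats a [histology_stats()] object.
#' @param D_ics,D_ecs intra-/extra-cellular diffusivities (um^2/ms).
#' @param kappa membrane permeability (um/ms) for every internal interface.
#' @param first which compartment type comes first, `"ICS"` (default) or `"ECS"`.
#' @return a `pw_domain` with `labels` set to `"ICS"`/`"ECS"`.
#' @export
synthesize_histology_domain <- function(stats = histology_stats(),
                                        D_ics = 0.5, D_ecs = 2, kappa = 0.05,
                                        first = c("ICS", "ECS")) {
  if (!inherits(stats, "pw_histology_stats")) stop("expected 'pw_histology_stats'")
  first <- match.arg(first)
  lengths <- numeric(0)
  labels <- character(0)
  total <- 0
  kind <- first
  repeat {
    len <- if (kind == "ICS") sample_ics_diameters(1L, stats)
           else stats::runif(1L, stats$ecs_range[1L], stats$ecs_range[2L])
    if (total + len >= stats$total_length) {
      len <- stats$total_length - total   # truncate the last drawn compartment
      if (len > 0) {
        lengths <- c(lengths, len)
        labels <- c(labels, kind)
      }
      break
    }
    lengths <- c(lengths, len)
    labels <- c(labels, kind)
    total <- total + len
    kind <- if (kind == "ICS") "ECS" else "ICS"
  }
  D <- ifelse(labels == "ICS", D_ics, D_ecs)
  build_domain(lengths, D, rep(kappa, length(lengths) - 1L), labels = labels)
}
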