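# Conservative finite-volume solver for the layered diffusion problem with
# membrane jump conditions. This is a verification oracle for the eigenmode
# propagator and the random-walk engine, not a performance surface: the
# membrane condition is applied between the two cells flanking each barrier
# face using cell-centre values (first-order locally, refined by resolution),
# and time stepping is theta-implicit (Crank-Nicolson by default) so accuracy
# is decoupled from stability limits.

# Build the grid (every barrier lies exactly on a cell face; widths uniform
# within a compartment) and the spatial operator A with dU/dt = A U.
fv_grid <- function(domain, resolution) {
  m <- length(domain$D)
  ncell <- pmax(1L, as.integer(round(domain$lengths * resolution)))
  h <- domain$lengths / ncell
  centers <- unlist(lapply(seq_len(m), function(i)
    domain$barriers[i] + h[i] * (seq_len(ncell[i]) - 0.5)))
  comp <- rep(seq_len(m), ncell)
  list(centers = centers, h = rep(h, ncell), comp = comp,
       ncell = ncell, first = cumsum(c(1L, ncell))[seq_len(m)])
}

fv_operator <- function(domain, grid) {
  n <- length(grid$centers)
  h <- grid$h
  ii <- jj <- integer(0); vv <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }
  for (k in seq_len(n - 1L)) {
    same <- grid$comp[k] == grid$comp[k + 1L]
    # conductance g of the face between cells k and k+1:
    # interior face flux  -D (U_{k+1} - U_k) / h; membrane face flux
    # kappa (U_k - U_{k+1}) between the flanking cell centres
    g <- if (same) domain$D[grid$comp[k]] / h[k]
         else domain$kappa[grid$comp[k] + 1L]
    add(k, k, -g / h[k]);          add(k, k + 1L, g / h[k])
    add(k + 1L, k + 1L, -g / h[k + 1L]); add(k + 1L, k, g / h[k + 1L])
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
}

#' Finite-volume solution of the layered diffusion problem
#'
#' Independent verification solver: conservative finite volumes with the
#' membrane jump condition applied across barrier faces and sealed
#' (zero-flux) ends, advanced by a theta-scheme (`theta = 0.5`,
#' Crank-Nicolson, by default). Total mass is conserved to round-off by
#' construction.
#'
#' @param domain a `pw_domain`.
#' @param ic initial condition, as in [analytical_flux()]: `"uniform_full"`,
#'   `list(mode = "delta", x0 = )`, or `list(mode = "uniform_interval", ...)`.
#'   A delta is realised as the cell average of the containing cell (split
#'   between flanking cells when `x0` falls on a face).
#' @param t_eval times (ms) at which to store the solution, ascending.
#' @param resolution cells per um (default 10).
#' @param dt_solver solver time step (ms, default 0.05).
#' @param theta implicitness weight (0.5 = Crank-Nicolson, 1 = backward Euler).
#' @return list of `pw_density_field`s (provenance `"fd_oracle"`), one per
#'   `t_eval`, each with the extra fields `comp` and `h`; the list carries the
#'   attributes `domain`, `grid` and `flux_series` (per-interface
#'   cell-flux history, see [fd_flux()]).
#' @export
fd_solve <- function(domain, ic, t_eval, resolution = 10, dt_solver = 0.05,
                     theta = 0.5) {
  assert_domain(domain)
  if (any(diff(t_eval) <= 0) || any(t_eval < 0)) stop("t_eval must be ascending and non-negative")
  grid <- fv_grid(domain, resolution)
  n <- length(grid$centers)
  A <- fv_operator(domain, grid)
  ic <- parse_seeding(ic)
  U <- switch(ic$mode,
    uniform_full = rep(steady_density(domain), n),
    delta = {
      u <- numeric(n)
      faces <- cumsum(c(domain$barriers[1L], grid$h))
      k <- findInterval(ic$x0, faces, rightmost.closed = TRUE)
      on_face <- any(abs(ic$x0 - faces[-c(1L, n + 1L)]) < 1e-9)
      if (on_face) {
        kf <- which(abs(ic$x0 - faces) < 1e-9)[1L] - 1L
        u[kf] <- 0.5 / grid$h[kf]
        u[kf + 1L] <- 0.5 / grid$h[kf + 1L]
      } else u[k] <- 1 / grid$h[k]
      u
    },
    uniform_interval = {
      faces <- cumsum(c(domain$barriers[1L], grid$h))
      # overlap of [a, b] with each cell
      lo <- pmax(faces[-(n + 1L)], ic$a); hi <- pmin(faces[-1L], ic$b)
      pmax(hi - lo, 0) / grid$h / (ic$b - ic$a)
    },
    stop("unsupported initial condition: ", ic$mode))
  nsteps <- as.integer(ceiling(max(t_eval) / dt_solver - 1e-9))
  I <- Matrix::Diagonal(n)
  M1 <- I - theta * dt_solver * A
  M2 <- I + (1 - theta) * dt_solver * A
  LU <- Matrix::lu(M1)
  # record the per-step membrane cell flux for fd_flux()
  m <- length(domain$D)
  ifc_left <- grid$first[-1L] - 1L      # cell just left of each internal barrier
  Jhist <- matrix(0, nsteps + 1L, max(m - 1L, 0L))
  ifc_flux <- function(u) domain$kappa[2:m] * (u[ifc_left] - u[ifc_left + 1L])
  if (m > 1L) Jhist[1L, ] <- ifc_flux(U)
  out <- vector("list", length(t_eval))
  store <- pmax(1L, as.integer(round(t_eval / dt_solver)))
  nxt <- 1L
  if (any(t_eval == 0)) {
    out[[1L]] <- structure(list(x = grid$centers, U = U, t = 0,
                                provenance = "fd_oracle", comp = grid$comp,
                                h = grid$h), class = "pw_density_field")
    nxt <- 2L
  }
  for (k in seq_len(nsteps)) {
    U <- as.numeric(Matrix::solve(LU, M2 %*% U))
    if (m > 1L) Jhist[k + 1L, ] <- ifc_flux(U)
    while (nxt <= length(t_eval) && store[nxt] == k) {
      out[[nxt]] <- structure(list(x = grid$centers, U = U, t = k * dt_solver,
                                   provenance = "fd_oracle", comp = grid$comp,
                                   h = grid$h), class = "pw_density_field")
      nxt <- nxt + 1L
    }
  }
  if (nxt <= length(t_eval))
    stop("internal error: requested time beyond the stepped range")
  attr(out, "domain") <- domain
  attr(out, "grid") <- grid
  attr(out, "dt_solver") <- dt_solver
  attr(out, "Jhist") <- Jhist
  out
}

#' Membrane flux series from a finite-volume solution
#'
#' Evaluates `kappa (U_L - U_R)` on the cells flanking an internal barrier at
#' every solver step, with the cumulative flux by trapezoidal time
#' integration.
#'
#' @param solution result of [fd_solve()].
#' @param interface internal interface index.
#' @return a `pw_flux_series` with `source = "fd_oracle"`.
#' @export
fd_flux <- function(solution, interface) {
  Jhist <- attr(solution, "Jhist")
  dt <- attr(solution, "dt_solver")
  if (is.null(Jhist)) stop("expected the list returned by fd_solve()")
  if (interface < 1L || interface > ncol(Jhist)) stop("interface out of range")
  J <- Jhist[, interface]
  tt <- (seq_along(J) - 1L) * dt
  cum <- c(0, cumsum(dt * (J[-1L] + J[-length(J)]) / 2))
  structure(list(times = tt, J = J, cumulative = cum, interface = interface,
                 source = "fd_oracle", Jfun = NULL, cumfun = NULL, dt = dt),
            class = "pw_flux_series")
}

#' Compartment masses of a density field
#'
#' Integrates a [fd_solve()] field over each compartment (exact cell sums).
#'
#' @param field a `pw_density_field` produced by [fd_solve()].
#' @return numeric vector of per-compartment masses (fractions).
#' @export
compartment_masses <- function(field) {
  if (is.null(field$comp)) stop("field does not carry cell metadata")
  as.numeric(tapply(field$U * field$h, field$comp, sum))
}
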