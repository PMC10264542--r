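#' Solver configuration for the drift-diffusion equation
#'
#' @param D Diffusion coefficient, cm^2/s. The default 8.2e-6 cm^2/s
#'   (820 um^2/s) is the aqueous/membrane value used throughout for the
#'   azide system.
#' @param dt Time step, s. If `NULL`, [steady_state_flux()] chooses
#'   0.9 dx^2/(2D) for the explicit scheme and d^2/(20 D) for the
#'   implicit scheme.
#' @param scheme `"implicit"` (backward Euler, tridiagonal,
#'   unconditionally stable; default) or `"explicit"` (forward Euler,
#'   subject to the stability bound of [check_stability()]).
#' @param boundary `"dirichlet"` (outermost reservoir cells pinned at
#'   `u_donor` / `u_acceptor`) or `"reflecting"` (zero flux, mass
#'   conserving).
#' @param u_donor,u_acceptor Pinned concentrations for Dirichlet runs
#'   (arbitrary units; permeability is independent of their scale).
#' @param steady_tol Relative change of the outlet flux between
#'   successive checks below which (together with `flux_agree_tol`) the
#'   run is declared steady.
#' @param flux_agree_tol Maximum relative disagreement between the
#'   membrane inlet and outlet fluxes at steady state.
#' @param check_interval Steps between steady-state checks.
#' @param max_steps Step budget before a run is flagged non-converged.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(D = 8.2e-6, dt = NULL,
                          scheme = c("implicit", "explicit"),
                          boundary = c("dirichlet", "reflecting"),
                          u_donor = 1, u_acceptor = 0,
                          steady_tol = 1e-9, flux_agree_tol = 1e-6,
                          check_interval = 1000L, max_steps = 5e7) {
  scheme <- match.arg(scheme)
  boundary <- match.arg(boundary)
  stopifnot(D > 0, is.null(dt) || dt > 0, steady_tol > 0,
            flux_agree_tol > 0, check_interval >= 1, max_steps >= 1)
  structure(list(D = D, dt = dt, scheme = scheme, boundary = boundary,
                 u_donor = u_donor, u_acceptor = u_acceptor,
                 steady_tol = steady_tol, flux_agree_tol = flux_agree_tol,
                 check_interval = as.integer(check_interval),
                 max_steps = max_steps),
            class = "solver_config")
}

#' Explicit-scheme stability bound
#'
#' The forward-Euler scheme for diffusion is stable only for
#' \eqn{dt \le dx^2/(2D)}; this returns that bound scaled by a 0.9
#' safety factor. Explicit runs with a larger `dt` are refused.
#'
#' @param config A [solver_config()] (or bare D, cm^2/s).
#' @param dx Grid spacing, cm.
#' @return Maximal stable time step, s.
#' @examples
#' check_stability(solver_config(D = 8.2e-6), dx = 1e-4)  # ~5.5e-4 s
#' @export
check_stability <- function(config, dx) {
  D <- if (inherits(config, "solver_config")) config$D else as.numeric(config)
  stopifnot(dx > 0, D > 0)
  0.9 * dx^2 / (2 * D)
}

#' Concentration state on a profile grid
#'
#' @param u Concentration per cell (arbitrary units), non-negative.
#' @param t_elapsed Elapsed simulated time, s.
#' @return An object of class `concentration_state`.
#' @export
concentration_state <- function(u, t_elapsed = 0) {
  if (any(!is.finite(u)) || any(u < 0))
    stop("concentrations must be finite and non-negative")
  structure(list(u = as.numeric(u), t_elapsed = t_elapsed),
            class = "concentration_state")
}

# Face weights for the symmetric thermodynamic flux discretization.
.face_weights <- function(G, kBT) {
  dG <- diff(G) / (2 * kBT)
  list(wl = exp(-dG), wr = exp(dG))
}

.resolve_dt <- function(config, profile) {
  if (!is.null(config$dt)) return(config$dt)
  if (config$scheme == "explicit") check_stability(config, profile$dx)
  else profile$d^2 / (20 * config$D)
}

#' Advance the Smoluchowski equation by a fixed number of steps
#'
#' Integrates
#' \deqn{\partial_t u = \nabla\!\cdot\!\left[D\left(\nabla u +
#'   u\,\nabla G/k_BT\right)\right]}
#' on the profile grid. The inter-cell flux uses symmetric exponential
#' (thermodynamic) weighting, which reduces to central-difference Fick
#' flux where G is constant and admits the Boltzmann distribution as an
#' exact stationary state under reflecting boundaries.
#'
#' @param state A [concentration_state()] on the same grid as `profile`.
#' @param profile An `energy_profile`.
#' @param config A [solver_config()].
#' @param n_steps Number of time steps to take.
#' @param thermo A [thermo_context()] or bare kBT (kcal/mol).
#' @return The advanced `concentration_state`.
#' @export
propagate <- function(state, profile, config, n_steps,
                      thermo = thermo_context()) {
  stopifnot(inherits(state, "concentration_state"),
            inherits(profile, "energy_profile"),
            inherits(config, "solver_config"), n_steps >= 0)
  n <- length(profile$G)
  if (length(state$u) != n)
    stop("state and profile are on different grids")
  dt <- .resolve_dt(config, profile)
  if (config$scheme == "explicit") {
    dt_max <- check_stability(config, profile$dx)
    if (dt > dt_max)
      stop(sprintf("dt = %g s exceeds the explicit stability bound %g s; reduce dt or use scheme = 'implicit'", dt, dt_max))
  }
  w <- .face_weights(profile$G, .kbt(thermo))
  res <- smol_run_cpp(state$u, w$wl, w$wr, config$D, profile$dx, dt,
                      scheme = if (config$scheme == "explicit") 0L else 1L,
                      boundary = if (config$boundary == "reflecting") 0L else 1L,
                      n_steps_target = as.numeric(n_steps),
                      max_steps = as.numeric(n_steps),
                      check_interval = config$check_interval,
                      steady_tol = config$steady_tol,
                      flux_agree_tol = config$flux_agree_tol,
                      face_in = 0L, face_out = n - 2L)
  concentration_state(pmax(res$u, 0), state$t_elapsed + n_steps * dt)
}

#' Steady-state flux, permeability and rate constant
#'
#' Runs the drift-diffusion solver with Dirichlet boundaries (donor
#' reservoir edge pinned at `u_donor`, acceptor edge at `u_acceptor`,
#' initial condition: donor reservoir filled, everything else empty)
#' until the membrane outlet flux is steady, then reports:
#' \describe{
#'   \item{`flux`}{Steady-state flux at the acceptor-side membrane face
#'     (concentration units x cm/s).}
#'   \item{`P`}{Membrane permeability, cm/s: `|flux|` divided by the
#'     difference of Boltzmann-weighted concentrations
#'     \eqn{\tilde u = u\,e^{G/k_BT}} extrapolated to the two membrane
#'     faces. This excludes the series resistance of the explicit water
#'     reservoirs, so for a flat profile it equals D/d exactly and in
#'     general it matches the solubility-diffusion integral over the
#'     membrane (see [analytic_permeability()]).}
#'   \item{`P_apparent`}{`|flux| / (u_donor - u_acceptor)`: the apparent
#'     permeability of membrane plus reservoirs (unstirred layers).}
#'   \item{`k`}{Permeation rate constant `P/d`, 1/s.}
#' }
#'
#' @param profile An `energy_profile` (donor plateau is the reference,
#'   G = 0).
#' @param config A [solver_config()]; `boundary` must be `"dirichlet"`.
#' @param thermo A [thermo_context()] or bare kBT (kcal/mol).
#' @return An object of class `smol_result`.
#' @examples
#' pr <- discretize_profile(c(0, 0, 0), d = 1e-4, dx = 2e-6)
#' res <- steady_state_flux(pr, solver_config(dt = 1e-4))
#' res$P * pr$d / solver_config()$D  # ~1: flat profile gives P = D/d
#' @export
steady_state_flux <- function(profile, config = solver_config(),
                              thermo = thermo_context()) {
  stopifnot(inherits(profile, "energy_profile"),
            inherits(config, "solver_config"))
  if (config$boundary != "dirichlet")
    stop("steady_state_flux needs Dirichlet boundaries")
  kBT <- .kbt(thermo)
  n <- length(profile$G)
  n_res <- profile$n_reservoir
  dt <- .resolve_dt(config, profile)
  if (config$scheme == "explicit") {
    dt_max <- check_stability(config, profile$dx)
    if (dt > dt_max)
      stop(sprintf("dt = %g s exceeds the explicit stability bound %g s; reduce dt or use scheme = 'implicit'", dt, dt_max))
  }
  u0 <- numeric(n)
  u0[seq_len(n_res)] <- config$u_donor
  u0[n] <- config$u_acceptor

  w <- .face_weights(profile$G, kBT)
  face_in <- n_res            # 1-based face between cells n_res, n_res+1
  face_out <- n_res + profile$n_membrane
  res <- smol_run_cpp(u0, w$wl, w$wr, config$D, profile$dx, dt,
                      scheme = if (config$scheme == "explicit") 0L else 1L,
                      boundary = 1L,
                      n_steps_target = -1,
                      max_steps = as.numeric(config$max_steps),
                      check_interval = config$check_interval,
                      steady_tol = config$steady_tol,
                      flux_agree_tol = config$flux_agree_tol,
                      face_in = face_in - 1L, face_out = face_out - 1L)
  if (!res$converged)
    warning(sprintf("steady state not reached within %g steps", config$max_steps))

  u <- res$u
  j <- res$flux_out
  # Boltzmann-weighted concentration extrapolated to the membrane faces:
  # u~ = u exp(G/kBT) drops by j * R across each face resistance
  # R = (dx/D) exp((G_i + G_{i+1})/2kBT); half a face from cell center
  # to the face itself.
  ut <- u * exp(profile$G / kBT)
  Rface <- function(f) (profile$dx / config$D) *
    exp((profile$G[f] + profile$G[f + 1]) / (2 * kBT))
  ut_face_d <- ut[face_in] - j * Rface(face_in) / 2
  ut_face_a <- ut[face_out + 1] + j * Rface(face_out) / 2
  dc_mem <- ut_face_d - ut_face_a
  P <- abs(j) / abs(dc_mem)
  P_apparent <- abs(j) / abs(config$u_donor - config$u_acceptor)

  structure(list(flux = j, P = P, P_apparent = P_apparent,
                 k = P / profile$d,
                 u_final = concentration_state(pmax(u, 0),
                                               res$steps * dt),
                 steps_taken = res$steps, converged = res$converged,
                 flux_in = res$flux_in, dt = dt, profile = profile,
                 config = config),
            class = "smol_result")
}

#' @export
print.smol_result <- function(x, ...) {
  cat("Smoluchowski steady-state permeation\n")
  cat(sprintf("  membrane %g cm, D = %g cm^2/s, %s scheme, dt = %g s\n",
              x$profile$d, x$config$D, x$config$scheme, x$dt))
  cat(sprintf("  converged: %s after %.3g steps (%.3g s simulated)\n",
              x$converged, x$steps_taken, x$steps_taken * x$dt))
  cat(sprintf("  flux          = %.6g conc.cm/s\n", x$flux))
  cat(sprintf("  P (membrane)  = %.6g cm/s   (logP = %.3f)\n",
              x$P, log10(x$P)))
  cat(sprintf("  P (apparent)  = %.6g cm/s   incl. reservoir layers\n",
              x$P_apparent))
  cat(sprintf("  k = P/d       = %.6g 1/s\n", x$k))
  invisible(x)
}

#' Solubility-diffusion permeability (closed-form oracle)
#'
#' The inhomogeneous solubility-diffusion model gives the steady-state
#' membrane permeability as
#' \deqn{1/P = \int_0^d \frac{e^{G(x)/k_BT}}{D}\,dx,}
#' evaluated here by the midpoint rule on the membrane cells of the
#' profile grid. This is the independent cross-check for
#' [steady_state_flux()].
#'
#' @param profile An `energy_profile` with the donor plateau as the
#'   reference (G = 0).
#' @param config A [solver_config()] (only `D` is used) or bare D in
#'   cm^2/s.
#' @param thermo A [thermo_context()] or bare kBT (kcal/mol).
#' @return Permeability, cm/s.
#' @examples
#' pr <- discretize_profile(c(0, 3.288, 0.253), d = 125e-4, dx = 1e-4)
#' analytic_permeability(pr, solver_config())
#' @export
analytic_permeability <- function(profile, config = solver_config(),
                                  thermo = thermo_context()) {
  stopifnot(inherits(profile, "energy_profile"))
  D <- if (inherits(config, "solver_config")) config$D else as.numeric(config)
  kBT <- .kbt(thermo)
  mem <- profile$region == "membrane"
  1 / sum(exp(profile$G[mem] / kBT) * profile$dx / D)
}

#' Boltzmann equilibrium distribution on a profile
#'
#' \eqn{u_i \propto e^{-G_i/k_BT}}, normalized so that
#' \eqn{\sum_i u_i\,dx} equals `total_mass`. This is the exact stationary
#' state of [propagate()] under reflecting boundaries.
#'
#' @inheritParams analytic_permeability
#' @param total_mass Total mass (concentration x length) on the grid.
#' @return A [concentration_state()].
#' @export
equilibrium_distribution <- function(profile, thermo = thermo_context(),
                                     total_mass = 1) {
  stopifnot(inherits(profile, "energy_profile"))
  kBT <- .kbt(thermo)
  u <- exp(-profile$G / kBT)
  concentration_state(u * total_mass / (sum(u) * profile$dx))
}
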