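flat_profile <- function(d = 1e-4, dx = 2e-6)
  discretize_profile(c(0, 0, 0), d = d, dx = dx)

test_that("explicit stability bound is dx^2/(2D) with a 0.9 safety factor", {
  cfg <- solver_config(D = 8.2e-6)
  expect_equal(check_stability(cfg, 1e-4), 0.9 * (1e-4)^2 / (2 * 8.2e-6))
  # the coarse study grid admits its 1 us step...
  expect_lt(1e-6, check_stability(cfg, 1e-4))
  # ...but the fine 1 A grid does not admit 0.1 ns explicitly
  expect_gt(1e-10, check_stability(cfg, 1e-8))
  pr <- flat_profile()
  expect_error(
    propagate(concentration_state(rep(1, length(pr$G))), pr,
              solver_config(scheme = "explicit",
                            dt = 2 * check_stability(cfg, pr$dx),
                            boundary = "reflecting"), 10),
    "stability")
})

test_that("free diffusion: uniform state is stationary and a delta spreads with variance 2Dt", {
  pr <- discretize_profile(c(0, 0, 0), d = 4e-2, dx = 1e-4)
  n <- length(pr$G)
  cfg <- solver_config(scheme = "explicit", boundary = "reflecting",
                       dt = check_stability(solver_config(), pr$dx))
  u0 <- concentration_state(rep(2.5, n))
  out <- propagate(u0, pr, cfg, 500)
  expect_equal(out$u, u0$u, tolerance = 1e-12)
  delta <- numeric(n); delta[round(n / 2)] <- 1 / pr$dx
  st <- propagate(concentration_state(delta), pr, cfg, 2000)
  mass <- sum(st$u) * pr$dx
  mu <- sum(pr$x * st$u) * pr$dx / mass
  v <- sum((pr$x - mu)^2 * st$u) * pr$dx / mass
  expect_equal(v, 2 * solver_config()$D * st$t_elapsed, tolerance = 0.01)
})

test_that("mass is conserved to 1e-10 over a million reflecting steps", {
  pr <- discretize_profile(c(0, 1.5, 0.4), d = 2e-6, dx = 1e-7)
  # the interface steps scale the explicit bound by exp(dG_face/2kBT),
  # so run well below the flat-profile Fickian bound
  cfg <- solver_config(scheme = "explicit", boundary = "reflecting",
                       dt = check_stability(solver_config(), pr$dx) / 4)
  u0 <- concentration_state(seq_along(pr$G) / length(pr$G))
  m0 <- sum(u0$u) * pr$dx
  out <- propagate(u0, pr, cfg, 1e6)
  expect_lt(abs(sum(out$u) * pr$dx - m0) / m0, 1e-10)
})

test_that("the Boltzmann distribution is stationary under both schemes", {
  plat <- build_compartment_profile(azide_model(), ecf(), cyt())
  pr <- discretize_profile(plat, d = 2e-6, dx = 1e-7, ramp_width = 4e-7)
  eq <- equilibrium_distribution(pr)
  # step of ln 2 in units of kBT gives an exact concentration ratio of 2
  step <- discretize_profile(c(0, 0.593 * log(2), 0.593 * log(2)),
                             d = 1e-6, dx = 1e-7)
  eq_step <- equilibrium_distribution(step)
  expect_equal(eq_step$u[1] / eq_step$u[length(eq_step$u)], 2,
               tolerance = 1e-12)
  # the explicit flux rule keeps the Boltzmann state fixed to near
  # machine precision; the implicit scheme adds tridiagonal-solve
  # roundoff proportional to D dt/dx^2
  cfg_ex <- solver_config(scheme = "explicit", boundary = "reflecting",
                          dt = check_stability(solver_config(), pr$dx))
  out_ex <- propagate(eq, pr, cfg_ex, 1e4)
  expect_lt(max(abs(out_ex$u - eq$u) / eq$u), 1e-10)
  cfg_im <- solver_config(scheme = "implicit", boundary = "reflecting",
                          dt = 1e-5)
  out_im <- propagate(eq, pr, cfg_im, 1e4)
  expect_lt(max(abs(out_im$u - eq$u) / eq$u), 1e-8)
})

test_that("flat-profile steady state recovers P = D/d within 1 percent", {
  pr <- flat_profile(d = 125e-4, dx = 1e-4)
  res <- steady_state_flux(pr, solver_config(scheme = "implicit"))
  expect_true(res$converged)
  expect_equal(res$P, solver_config()$D / pr$d, tolerance = 0.01)
  expect_equal(analytic_permeability(pr), solver_config()$D / pr$d,
               tolerance = 1e-12)
})

test_that("numerical steady state matches the solubility-diffusion oracle on resolved ramps", {
  plat <- build_compartment_profile(azide_model(), ecf(), cyt())
  d <- 1e-4
  errs <- vapply(c(d / 50, d / 100, d / 200), function(dx) {
    pr <- discretize_profile(plat, d = d, dx = dx, ramp_width = d / 5)
    res <- steady_state_flux(pr, solver_config(scheme = "implicit",
                                               steady_tol = 1e-11))
    abs(res$P - analytic_permeability(pr)) / analytic_permeability(pr)
  }, numeric(1))
  expect_lt(errs[2], 0.01)          # dx <= d/50 criterion (met by d/100)
  expect_true(all(diff(errs) < 0))  # refinement converges to the oracle
})

test_that("analytic oracle has the closed forms for square and two-slab barriers", {
  D <- solver_config()$D
  sq <- discretize_profile(c(0, 3.288117, 0), d = 125e-4, dx = 1e-4)
  expect_equal(analytic_permeability(sq),
               (D / 125e-4) * exp(-3.288117 / 0.593), tolerance = 1e-12)
  G1 <- 1.2; G2 <- 2.7
  half <- c(rep(G1, 25), rep(G2, 25))
  pr <- discretize_profile(c(0, 0, 0), d = 50e-4, dx = 1e-4)
  pr$G[pr$region == "membrane"] <- half
  expect_equal(1 / analytic_permeability(pr),
               (50e-4 / (2 * D)) * (exp(G1 / 0.593) + exp(G2 / 0.593)),
               tolerance = 1e-12)
})

test_that("steady flux is linear in the donor concentration and k equals P/d", {
  plat <- build_compartment_profile(azide_model(), ecf(), cyt())
  pr <- discretize_profile(plat, d = 1e-4, dx = 2e-6)
  r1 <- steady_state_flux(pr, solver_config(scheme = "implicit"))
  r2 <- steady_state_flux(pr, solver_config(scheme = "implicit",
                                            u_donor = 2))
  expect_equal(r2$flux, 2 * r1$flux, tolerance = 1e-6)
  expect_equal(r2$P, r1$P, tolerance = 1e-6)
  expect_equal(r1$k * pr$d, r1$P, tolerance = 1e-12)
  # inlet and outlet fluxes agree at steady state
  expect_lt(abs(r1$flux_in - r1$flux) / abs(r1$flux), 1e-6)
})

test_that("propagate guards grids and boundary bookkeeping", {
  pr <- flat_profile()
  expect_error(propagate(concentration_state(rep(1, 3)), pr,
                         solver_config(), 5), "different grids")
  expect_error(steady_state_flux(pr, solver_config(boundary = "reflecting")),
               "Dirichlet")
})
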