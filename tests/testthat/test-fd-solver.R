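test_that("cfl_bound follows dx^2/(2 eps^2) with the safety factor", {
  g <- trait_grid(80, 1600)  # dx = 0.05
  expect_equal(cfl_bound(g, 0.1), 0.1125)
  expect_equal(cfl_bound(g, 0.05), 0.45)
  eps <- c(0.05, 0.1, 0.2, 0.4)
  expect_true(all(diff(vapply(eps, function(e) cfl_bound(g, e),
                              numeric(1))) < 0))
})

test_that("explicit step reduces to the exact update on degenerate inputs", {
  g <- trait_grid(80, 160)
  flat <- flat_landscape(g = 1.2)
  n <- rep(1, g$Nx)
  st <- population_state(n, g)
  dt <- 0.01
  new <- step_explicit(st, flat, dt, epsilon = 0.1)
  inner <- which(g$x > 10 & g$x < 70)[-1]
  # uniform interior: the diffusion term vanishes, update is 1 + dt (g - rho)
  expect_equal(new$density[inner],
               rep(1 + dt * (1.2 - st$rho), length(inner)))
  # zero density is a fixed point
  z <- population_state(rep(0, g$Nx), g)
  expect_equal(step_explicit(z, flat, dt, 0.1)$density, rep(0, g$Nx))
})

test_that("an interior spike conserves mass to machine precision when a = 0", {
  g <- trait_grid(80, 800)
  null_ls <- custom_landscape(function(x) rep(0, length(x)), d = 0,
                              support_lo = 30, support_hi = 50)
  n <- rep(0, g$Nx); n[400] <- 1e-8   # rho ~ 1e-9: competition negligible
  st <- population_state(n, g)
  for (k in 1:20) st <- step_explicit(st, null_ls, dt = 0.2, epsilon = 0.1)
  expect_equal(st$rho, 1e-8 * g$dx, tolerance = 1e-7)
})

test_that("the corrected mode enforces the CFL bound", {
  g <- trait_grid(80, 1600)
  st <- population_state(init_gaussian()(g$x), g)
  expect_error(step_explicit(st, peak1(), dt = 0.2, epsilon = 0.1), "CFL")
  expect_silent(step_explicit(st, peak1(), dt = 0.1, epsilon = 0.1))
})

test_that("paper_literal mode applies the printed update verbatim", {
  g <- trait_grid(80, 160)
  ls <- peak1()
  n <- init_gaussian()(g$x); n[c(1, g$Nx)] <- 0
  st <- population_state(n, g)
  dt <- 1e-4
  new <- step_explicit(st, ls, dt, epsilon = 0.1, mode = "paper_literal")
  j <- 2:(g$Nx - 1)
  a_next <- eval_landscape(ls, g$x, dt)
  manual <- n[j] + (dt / g$dx^2) * (n[j + 1] - 2 * n[j] + n[j - 1]) +
    dt * n[j] * a_next[j]
  expect_equal(new$density[j], manual)
})

test_that("flat-landscape mass follows the logistic oracle within 1%", {
  g <- grid_default()
  flat <- flat_landscape(g = 1.5)
  n0 <- rep(0, g$Nx); n0[g$x > 15 & g$x < 65] <- 0.02
  traj <- fd_run(flat, n0, g, T = 50)
  ref <- logistic_mass(traj$times, traj$rho[1], 1.5)
  expect_lt(max(abs(traj$rho - ref) / ref), 0.01)
})

test_that("density stays nonnegative along the run", {
  g <- grid_default()
  traj <- fd_run(peak1(), attr(peak1(), "n0"), g, T = 10)
  for (st in traj$snapshots) expect_true(all(st$density >= 0))
})

test_that("halving dx and dt changes the mass limit by under 1%", {
  ls4 <- preset_landscape("fig4")
  n0 <- attr(ls4, "n0")
  r1 <- fd_run(ls4, n0, trait_grid(80, 1600), T = 20, dt = 0.05)
  r2 <- fd_run(ls4, n0, trait_grid(80, 3200), T = 20, dt = 0.025)
  expect_lt(abs(r1$rho[length(r1$rho)] - r2$rho[length(r2$rho)]) /
              r2$rho[length(r2$rho)], 0.01)
})

test_that("lab and co-moving frames agree on the mass history within 2%", {
  g <- grid_default()
  p1 <- peak1()
  tl <- fd_run(p1, attr(p1, "n0"), g, T = 20, frame = "lab")
  tc <- fd_run(p1, attr(p1, "n0"), g, T = 20, frame = "comoving")
  expect_lt(abs(tl$rho[length(tl$rho)] - tc$rho[length(tc$rho)]) /
              tl$rho[length(tl$rho)], 0.02)
})

test_that("runs abort when the shifted support approaches the boundary", {
  g <- grid_default()
  expect_error(fd_run(peak1(), attr(peak1(), "n0"), g, T = 400),
               "boundary")
})
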