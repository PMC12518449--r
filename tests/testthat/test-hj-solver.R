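test_that("the numerical Hamiltonian takes the printed branch values", {
  expect_equal(hamiltonian(1, 1), 1)     # H+ active
  expect_equal(hamiltonian(-1, 1), 0)    # both branches off
  expect_equal(hamiltonian(-1, -1), 1)   # H- active
  # monotone-scheme property: nondecreasing in p, nonincreasing in q
  set.seed(42)
  p <- runif(200, -3, 3); q <- runif(200, -3, 3); h <- runif(200, 0, 0.5)
  expect_true(all(hamiltonian(p + h, q) >= hamiltonian(p, q)))
  expect_true(all(hamiltonian(p, q + h) <= hamiltonian(p, q)))
})

test_that("a constant phase with a = rho is stationary for the eps-scheme", {
  g <- trait_grid(80, 160)
  eps <- 0.1; target_rho <- 1.25
  u0 <- rep(-eps * log(target_rho / g$L), g$Nx)
  flat <- custom_landscape(function(x) rep(target_rho + 0.5, length(x)),
                          d = 0.5, support_lo = 0, support_hi = 80)
  st <- hj_state(u0, g, epsilon = eps)
  expect_equal(st$mass, target_rho, tolerance = 1e-12)
  new <- hj_step_eps(st, flat, dt = 0.01, c = 1)
  # H(-c/2, -c/2) = c^2/4 cancels the c^2/4 shift; a - rho = 0 closes it
  expect_equal(new$phase, u0, tolerance = 1e-12)
})

test_that("the caption initial phase reproduces the initial mass", {
  g <- grid_default()
  st <- hj_state(u0_fig5(0.1)(g$x), g, epsilon = 0.1)
  # rho_0 = dx sum exp(-u0/eps) = integral of the caption Gaussian
  expect_equal(st$mass, sqrt(pi) * 10 / 10, tolerance = 1e-6)
})

test_that("phase slopes are consistent finite differences of smooth phases", {
  g <- trait_grid(80, 1600)
  u <- 0.02 * (g$x - 40)^2
  s <- shiftpeaks:::phase_slopes(u, g$dx)
  exact <- 0.04 * (g$x - 40)
  inner <- 2:(g$Nx - 1)   # ghost extrapolation makes the ends one-sided
  expect_lt(max(abs(((s$back + s$fwd) / 2 - exact)[inner])), 1e-9)
  expect_lt(max(abs(s$back - exact)), 0.0015)  # one-sided bias u''/2 * dx
  # halving dx halves the one-sided bias
  g2 <- trait_grid(80, 3200)
  s2 <- shiftpeaks:::phase_slopes(0.02 * (g2$x - 40)^2, g2$dx)
  b1 <- max(abs(s$back - exact))
  b2 <- max(abs(s2$back - 0.04 * (g2$x - 40)))
  expect_equal(b2 / b1, 0.5, tolerance = 0.05)
})

test_that("the limit multiplier root is the closed-form maximum", {
  g <- grid_default()
  ls5 <- preset_landscape("fig5")
  v <- v0_fig5()(g$x); v <- v - min(v)
  P <- hj_limit_multiplier(v, ls5, g, dt = 0.01, c = 1,
                           check_bisection = TRUE)  # errors on disagreement
  expect_true(is.finite(P))
  # shifting the fitness by a constant shifts P by exactly that constant
  ls5b <- preset_landscape("fig5"); ls5b$d <- ls5$d - 0.3
  expect_equal(hj_limit_multiplier(v, ls5b, g, dt = 0.01, c = 1), P + 0.3,
               tolerance = 1e-12)
})

test_that("the limit scheme enforces min v = 0 at every step", {
  g <- grid_default()
  ls5 <- preset_landscape("fig5")
  v <- v0_fig5()(g$x); v <- v - min(v)
  st <- hj_state(v, g, epsilon = NULL, mass = NA_real_)
  for (k in 1:50) {
    st <- hj_step_limit(st, ls5, dt = 0.004, c = 1)
    expect_identical(min(st$phase), 0)
  }
})

test_that("the limit multiplier and argmin converge to the lagged state", {
  g <- grid_default()
  ls5 <- preset_landscape("fig5")
  hjL <- hj_run(ls5, v0_fig5(), g, T = 12, c = 1, epsilon = NULL)
  m <- hjL$mass
  expect_lt(abs(m[length(m)] - m[length(m) - 1]), 1e-6)   # P_n fixed point
  expect_equal(m[length(m)], 7/4, tolerance = 5e-3)       # a_M - c^2/4
  # a further 100 steps move the argmin by less than dx
  st <- hjL$state
  a0 <- shiftpeaks:::phase_argmin(st$phase, g$x)
  for (k in 1:100) st <- hj_step_limit(st, ls5, dt = hjL$dt, c = 1)
  expect_lt(abs(shiftpeaks:::phase_argmin(st$phase, g$x) - a0), g$dx)
})

test_that("eps-scheme and co-moving FD densities agree at matched times", {
  # the HJ clock is tau = eps * t: tau = 1 corresponds to t = 10
  g <- grid_default()
  hjE <- hj_run(preset_landscape("fig5"), u0_fig5(0.1), g, T = 1, c = 1,
                epsilon = 0.1)
  ls4 <- preset_landscape("fig4")
  tfd <- fd_run(ls4, attr(ls4, "n0"), g, T = 10, frame = "comoving")
  fin <- tfd$snapshots[[length(tfd$snapshots)]]
  am_fd <- fin$grid$x[which.max(fin$density)]
  am_hj <- shiftpeaks:::phase_argmin(hjE$state$phase, g$x)
  expect_lt(abs(am_fd - am_hj), 2 * g$dx)
})
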