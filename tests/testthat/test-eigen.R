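test_that("constant-potential eigenpair matches the closed form", {
  # lambda = eps^2 pi^2 / (2R)^2 - g, eigenvector ~ cos(pi x / (2R))
  for (prm in list(c(eps = 0.3, R = 5, g = 2), c(eps = 0.2, R = 4, g = 1))) {
    sp <- eigen_spec(function(x) rep(prm["g"], length(x)),
                     epsilon = prm[["eps"]], R = prm[["R"]], dx = 0.005)
    pr <- principal_eigenpair_dirichlet(sp, normalization = "sup_one")
    exact <- prm[["eps"]]^2 * pi^2 / (2 * prm[["R"]])^2 - prm[["g"]]
    expect_equal(pr$lambda, exact, tolerance = 1e-4)
    expect_lt(max(abs(pr$vector - cos(pi * pr$x / (2 * prm[["R"]])))), 1e-3)
    expect_true(all(pr$vector > 0))
  }
})

test_that("shifting the potential by s shifts lambda by -s exactly", {
  pot <- function(x) pmax(1 - (x - 1)^2, 0)
  s1 <- eigen_spec(pot, 0.1, 6); s2 <- eigen_spec(function(x) pot(x) + 0.7,
                                                  0.1, 6)
  p1 <- principal_eigenpair_dirichlet(s1)
  p2 <- principal_eigenpair_dirichlet(s2)
  expect_equal(p2$lambda, p1$lambda - 0.7, tolerance = 1e-10)
  expect_equal(p2$vector, p1$vector, tolerance = 1e-7)
})

test_that("the single-peak drift eigenvalue lies in the harmonic bracket", {
  # Rayleigh lower bound -(a_M - c^2/4) plus harmonic upper estimate
  pd <- principal_eigenpair_drift(peak1(), c = 1, epsilon = 0.1, R = 30)
  expect_gt(pd$lambda, -7/4)
  expect_lt(pd$lambda, -7/4 + 2 * 0.1)
})

test_that("similarity and direct drift solves agree; c = 0 is symmetric", {
  p1 <- peak1()
  sim <- principal_eigenpair_drift(p1, 1, 0.1, R = 30, dx = 0.01)
  expect_identical(sim$lambda, sim$symmetric_lambda)  # same spectrum, exactly
  dir <- principal_eigenpair_drift(p1, 1, 0.1, R = 30, dx = 0.01,
                                   method = "direct")
  expect_lt(abs(dir$lambda - sim$lambda), 1e-3)
  expect_true(all(dir$vector >= 0))
  # zero drift reduces to the plain Dirichlet problem with potential a
  z1 <- principal_eigenpair_drift(p1, 0, 0.1, R = 30)
  z2 <- principal_eigenpair_dirichlet(
    eigen_spec(function(x) eval_landscape(p1, x, 0), 0.1, 30, center = 40))
  expect_equal(z1$lambda, z2$lambda, tolerance = 1e-12)
})

test_that("lambda(R) is nonincreasing and stabilizes with the radius", {
  # constant potential: strict closed-form decrease
  lr <- lambda_R_curve(function(x) rep(1, length(x)), 0.2,
                       radii = c(2, 4, 8), dx = 0.01)
  expect_equal(lr$lambda, 0.2^2 * pi^2 / (2 * c(2, 4, 8))^2 - 1,
               tolerance = 1e-4)
  expect_true(all(diff(lr$lambda) < 0))
  # localized potential: stabilized long before the largest radius
  pot <- function(x) eval_landscape(peak1(), x, 0) - 1/4
  lrp <- lambda_R_curve(pot, 0.1, radii = c(5, 10, 20, 40), center = 40,
                        dx = 0.01)
  expect_true(all(diff(lrp$lambda) <= 1e-10))
  expect_lt(abs(lrp$lambda[4] - lrp$lambda[3]), 1e-8)
  # Rayleigh bound for every radius
  expect_true(all(lrp$lambda >= -max(pot(seq(10, 70, by = 0.01)))))
  # whole-line wrapper stabilizes to the same value
  wl <- principal_eigenpair_wholeline(pot, 0.1, R0 = 10, center = 40,
                                      dx = 0.01)
  expect_equal(wl$lambda, lrp$lambda[4], tolerance = 1e-8)
  expect_identical(wl$provenance, "whole_line_extrapolated")
})

test_that("the eigenvalue gap follows the harmonic asymptotic in epsilon", {
  el <- epsilon_limit_check(peak1(), 1, c(0.2, 0.1, 0.05), R = 30)
  expect_equal(attr(el, "limit_value"), -7/4)
  expect_true(all(el$gap > 0))
  expect_true(all(diff(el$gap) < 0))
  # |a''| = 2 at the quadratic peak: gap ~ eps within 25%
  expect_true(all(abs(el$gap - el$epsilon) / el$epsilon < 0.25))
  # transformed c = 0 and c = 1 problems differ by a constant only
  el0 <- epsilon_limit_check(peak1(), 0, c(0.1), R = 30)
  expect_equal(el0$gap, el$gap[el$epsilon == 0.1], tolerance = 1e-8)
})

test_that("a supercritical speed flips the eigenvalue sign (extinction)", {
  el <- epsilon_limit_check(peak1(), 4, c(0.2, 0.1), R = 30)
  expect_true(all(el$lambda > 0))   # a_M - c^2/4 = -2 < 0
})

test_that("decay envelopes hold for the drift eigenvector", {
  ps <- principal_eigenpair_drift(peak1(), 1, 0.1, R = 30,
                                  normalization = "sup_one")
  env <- decay_envelope_check(ps, peak1(), 1)
  expect_gt(env$n_checked, 100)
  expect_identical(env$n_upper_violations, 0L)
  expect_identical(env$n_lower_violations, 0L)
  # printed envelope value: at |x| = R0 + eps log(2)/kappa_bar the bound is 1/2
  x_half <- 41.5811 + 0.1 * log(2) / env$kappa_bar
  expect_equal(exp(-env$kappa_bar * (x_half - 41.5811) / 0.1), 1/2,
               tolerance = 1e-4)
  # c = 0: the two envelope rates are symmetric about the peak
  ps0 <- principal_eigenpair_drift(peak1(), 0, 0.1, R = 30,
                                   normalization = "sup_one")
  env0 <- decay_envelope_check(ps0, peak1(), 0)
  expect_identical(env0$n_upper_violations, 0L)
  expect_identical(env0$n_lower_violations, 0L)
})

test_that("the mass identity integral a p = -lambda holds to 1e-3", {
  pd <- principal_eigenpair_drift(peak1(), 1, 0.1, R = 30)
  mi <- mass_identity_check(pd, peak1())
  expect_lt(mi$abs_gap, 1e-3)
})

test_that("two-speed persistence classification follows the minimal eigenvalue", {
  b1 <- make_bump(32, 7/4, 2, -1); b2 <- make_bump(48, 5/2, 2, 2.5)
  # c2 = 2.5: lagged fitnesses (3/2 - 1/2, 15/16 - 1/2) -> group 1 dominates
  cls <- persistence_classification(b1, b2, -1, 2.5, d = 1/2, epsilon = 0.1)
  expect_identical(cls$verdict, "persists")
  expect_identical(cls$dominant_index, 1L)
  expect_equal(cls$lagged_fitness, c(1, 0.4375))
  expect_equal(cls$lambda_limit, -c(1, 0.4375))
  # c2 = 1: lagged fitness of peak 2 becomes 7/4 > 1 -> group 2 dominates
  b2s <- make_bump(48, 5/2, 2, 1)
  cls2 <- persistence_classification(b1, b2s, -1, 1, d = 1/2, epsilon = 0.1)
  expect_identical(cls2$dominant_index, 2L)
  expect_equal(cls2$lagged_fitness[2], 5/2 - 1/4 - 1/2)
  # both lagged fitnesses negative: extinction
  cls3 <- persistence_classification(make_bump(32, 7/4, 2, -4),
                                     make_bump(48, 5/2, 2, 4),
                                     -4, 4, d = 1/2, epsilon = 0.1)
  expect_identical(cls3$verdict, "extinct")
})

test_that("eigenvalues are invariant to normalization and mirror symmetry", {
  pL <- principal_eigenpair_drift(peak1(), 1, 0.1, R = 30)
  pS <- principal_eigenpair_drift(peak1(), 1, 0.1, R = 30,
                                  normalization = "sup_one")
  expect_identical(pL$lambda, pS$lambda)
  mirror <- compose_landscape(list(make_bump(-40, 5/2, 2, -1)), d = 1/2,
                              epsilon = 0.1)
  pM <- principal_eigenpair_drift(mirror, -1, 0.1, R = 30, center = -40)
  expect_equal(pM$lambda, pL$lambda, tolerance = 1e-10)
})

test_that("random positive trial vectors never beat the principal pair", {
  sp <- eigen_spec(function(x) eval_landscape(peak1(), x, 0) - 1/4,
                   0.1, 10, center = 40, dx = 0.02)
  pr <- principal_eigenpair_dirichlet(sp)
  nd_len <- length(pr$vector)
  set.seed(7)
  for (i in 1:10) {
    phi <- runif(nd_len) * exp(-abs(seq_len(nd_len) - nd_len / 2) / 100)
    expect_gte(rayleigh_quotient(sp, phi), pr$lambda - 1e-10)
  }
})
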