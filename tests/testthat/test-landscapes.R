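test_that("bump components evaluate to (h - (x - x0)^p)^+ with exact support", {
  b4 <- make_bump(35, 5/2, 4, 1)
  expect_equal(eval_bump(b4, 35), 2.5)
  b2 <- make_bump(40, 5/2, 2, 1)
  expect_equal(eval_bump(b2, 42), 0)          # (42-40)^2 = 4 > 5/2
  expect_equal(b2$half_width, sqrt(5/2))
  # no negative leakage, exact zero outside the closed support, continuity
  for (b in list(b4, b2)) {
    xs <- seq(b$center - 3, b$center + 3, by = 0.013)
    v <- eval_bump(b, xs)
    expect_true(all(v >= 0))
    expect_true(all(v[abs(xs - b$center) > b$half_width] == 0))
    edge <- eval_bump(b, b$center + b$half_width)
    expect_equal(edge, 0)
  }
})

test_that("bump construction rejects invalid exponents and heights", {
  expect_error(make_bump(0, 1, 3), "even integer")
  expect_error(make_bump(0, 1, 0), "even integer")
  expect_error(make_bump(0, -1, 2), "positive")
})

test_that("landscape composition matches the caption parameter sets", {
  ls4 <- preset_landscape("fig4")
  expect_equal(eval_landscape(ls4, 35, 0), 2.5 - 0.5)  # disjoint supports
  expect_equal(eval_landscape(ls4, 40, 0), 2)
  # shifted evaluation: the bump moves at eps*c per unit time
  expect_equal(eval_landscape(ls4, 35 + 0.1 * 1 * 7, 7), 2)
  expect_error(compose_landscape(list(), d = 0.5), "nonempty")
  expect_error(
    compose_landscape(list(make_bump(0, 1, 2, 1), make_bump(5, 1, 2, 2)),
                      d = 0.5, case_tag = "case2_diverging"),
    "c1 < 0 < c2")
  ls8 <- preset_landscape("fig8")   # c1 = -6/5 < 0 < c2 = 6/5
  expect_s3_class(ls8, "fitness_landscape")
})

test_that("global maxima and curvatures are exact for the presets", {
  gm <- global_maxima(preset_landscape("fig4"))
  expect_equal(gm$location, c(35, 40), tolerance = 1e-7)
  expect_equal(gm$value, c(2, 2))
  expect_equal(gm$curvature_magnitude, c(0, 2), tolerance = 1e-6)
  # overlapping supports (fig8): one merged peak, curvatures add
  gm8 <- global_maxima(preset_landscape("fig8"))
  expect_equal(gm8$location, 40, tolerance = 1e-7)
  expect_equal(gm8$value, 7/4 + 5/2 - 1/2)
  expect_equal(gm8$curvature_magnitude, 4, tolerance = 1e-6)
})

test_that("a flat-topped landscape fails the isolated-maxima assumption", {
  flat_top <- custom_landscape(function(x) pmin(1, pmax(2 - abs(x - 40), 0)),
                               d = 0.5, support_lo = 38, support_hi = 42)
  expect_error(global_maxima(flat_top), "flat top")
  rep <- validate_assumptions(flat_top, 0.5)
  expect_false(rep$pass[rep$assumption == "A4_finite_maxima"])
})

test_that("lagged optima solve a(x) = a_M - c^2/4 on the uphill side", {
  lo <- lagged_optima(peak1(), 1)
  expect_equal(lo$x_bar, 39.5, tolerance = 1e-9)
  expect_equal(lo$lagged_fitness, 7/4)
  lo4 <- lagged_optima(preset_landscape("fig4"), 1)
  expect_equal(lo4$x_bar, c(35 - 4^(-1/4), 39.5), tolerance = 1e-8)
  # level identity and slope sign at every lagged optimum
  ls4 <- preset_landscape("fig4")
  expect_true(all(abs(eval_landscape(ls4, lo4$x_bar, 0) -
                        lo4$lagged_fitness) < 1e-9))
  expect_true(all(lo4$slope > 0))
  # zero speed: the lag collapses onto the peaks
  lo0 <- lagged_optima(ls4, 0)
  expect_equal(lo0$x_bar, lo0$peak)
  # lag level below the off-support fitness: no lagged optima
  expect_equal(nrow(lagged_optima(peak1(), 4)), 0)
})

test_that("lagged optima converge to the peaks as c -> 0+", {
  # lag distance closed form: (c^2/4)^(1/p). The "error <= c" bound holds
  # for quadratic peaks (distance c/2); quartic peaks lag like sqrt(c/2),
  # so only the general (c^2/4)^(1/p) rate is asserted there.
  for (cc in c(0.5, 0.1, 0.01)) {
    lo1 <- lagged_optima(peak1(), cc)
    expect_true(all(abs(lo1$x_bar - lo1$peak) <= cc),
                label = paste("quadratic, c =", cc))
    lo4 <- lagged_optima(preset_landscape("fig4"), cc)
    expect_equal(abs(lo4$x_bar - lo4$peak),
                 (cc^2 / 4)^(1 / c(4, 2)), tolerance = 1e-6)
  }
})

test_that("assumption checker counts level crossings as required", {
  rep1 <- validate_assumptions(peak1(), 1)
  expect_true(all(rep1$pass))
  rep4 <- validate_assumptions(peak1(), 4)  # level below the landscape
  expect_false(rep4$pass[rep4$assumption == "A5_crossing_counts"])
  # every figure preset passes with its caption speeds (d <= 0 warns)
  expect_true(all(validate_assumptions(preset_landscape("fig4"), 1)$pass))
  expect_warning(r6 <- validate_assumptions(preset_landscape("fig6"),
                                            c(-1, 2.5)), "d <= 0")
  expect_true(all(r6$pass))
  r8 <- validate_assumptions(preset_landscape("fig8"), c(-6/5, 6/5))
  expect_true(all(r8$pass))
})

test_that("the default initial condition satisfies its decay envelope", {
  n0 <- init_gaussian()
  x <- seq(0.05, 80, by = 0.05)
  expect_true(validate_initial_condition(n0, x))
  expect_equal(n0(37.5), 1 / 10)
  bad <- function(x) rep(2, length(x))
  attr(bad, "C1") <- 0; attr(bad, "C2") <- 0.05
  expect_false(validate_initial_condition(bad, x))
})

test_that("unknown presets raise an error listing the available ones", {
  expect_error(preset_landscape("fig99"), "fig4")
})
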