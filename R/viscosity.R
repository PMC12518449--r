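# Limiting Hamilton-Jacobi analysis: the eikonal representation formula
# between consecutive maxima, the phase u = max{f1, f2}, and the selection of
# concentration points (positive-slope lagged optima; shallowest-peak
# refinement via |a''|).

#' Geodesic cost of the eikonal representation formula
#'
#' In one dimension, with monotone optimal paths, the optimal-control cost
#' between `x` and `y` reduces to
#' \deqn{L'(x, y) = -\left| \int_x^y \sqrt{a_M - a(s)}\, ds \right| \le 0,}
#' computed by adaptive quadrature split at the bump support edges (where the
#' integrand has integrable kinks).
#'
#' @param x,y endpoints.
#' @param landscape a `fitness_landscape` (frozen frame).
#' @param a_M the global maximum of \eqn{a}; computed when `NULL`.
#' @return The (nonpositive) cost.
#' @export
geodesic_cost <- function(x, y, landscape, a_M = NULL) {
  a_M <- a_M %||% max(global_maxima(landscape)$value)
  if (x == y) return(0)
  lo <- min(x, y); hi <- max(x, y)
  probe <- seq(lo, hi, length.out = 512)
  if (any(eval_landscape(landscape, probe, 0) > a_M + 1e-9))
    stop("a exceeds the supplied a_M on the path (inconsistent a_M)",
         call. = FALSE)
  integrand <- function(s) sqrt(pmax(a_M - eval_landscape(landscape, s, 0), 0))
  # split at support edges and centers inside the interval
  cuts <- sort(unique(c(lo, hi, unlist(lapply(landscape$components, function(b)
    c(b$center - b$half_width, b$center, b$center + b$half_width))))))
  cuts <- cuts[cuts >= lo & cuts <= hi]
  if (cuts[1] > lo) cuts <- c(lo, cuts)
  if (cuts[length(cuts)] < hi) cuts <- c(cuts, hi)
  total <- 0
  for (i in seq_len(length(cuts) - 1)) {
    if (cuts[i + 1] - cuts[i] < 1e-14) next
    total <- total + stats::integrate(integrand, cuts[i], cuts[i + 1],
                                      abs.tol = 1e-10,
                                      subdivisions = 400L)$value
  }
  -abs(total)
}

#' Brute-force geodesic cost (dynamic-programming oracle)
#'
#' Discrete minimization of \eqn{\sum_k \sqrt{a_M - a(\zeta_k)}
#' |\zeta_{k+1} - \zeta_k|} over monotone grid paths from `x` to `y`
#' (midpoint rule), negated. Independent of the quadrature path used by
#' [geodesic_cost()]; agreement is \eqn{O(\Delta x)}.
#'
#' @inheritParams geodesic_cost
#' @param dx path grid step.
#' @return The (nonpositive) cost.
#' @export
brute_force_cost <- function(x, y, landscape, dx = 1e-3, a_M = NULL) {
  a_M <- a_M %||% max(global_maxima(landscape)$value)
  if (x == y) return(0)
  lo <- min(x, y); hi <- max(x, y)
  m <- max(2L, ceiling((hi - lo) / dx))
  zeta <- seq(lo, hi, length.out = m + 1L)
  mid <- (zeta[-1] + zeta[-length(zeta)]) / 2
  step <- diff(zeta)
  -sum(sqrt(pmax(a_M - eval_landscape(landscape, mid, 0), 0)) * step)
}

#' Build the limiting phase on an interval between consecutive maxima
#'
#' On \eqn{[x_i, x_{i+1}]} the representation formula gives
#' \eqn{u = \max\{f_1, f_2\}} with the decreasing branch
#' \eqn{f_1(x) = u(x_i) - \int_{x_i}^x \sqrt{a_M - a}} and the increasing
#' branch \eqn{f_2(x) = u(x_{i+1}) - \int_x^{x_{i+1}} \sqrt{a_M - a}}.
#' The boundary values are inputs (the limit problem does not determine the
#' global constants uniquely).
#'
#' @param landscape a `fitness_landscape` (frozen frame).
#' @param interval numeric length-2: consecutive global maxima
#'   \eqn{(x_i, x_{i+1})}; for a single-peak outer interval pass the outer
#'   endpoint and the peak.
#' @param boundary_values numeric length-2: \eqn{u(x_i)}, \eqn{u(x_{i+1})}.
#' @param n_grid evaluation-grid size.
#' @return A `phase_function`: grid `x`, branches `f1`, `f2`, phase `u`
#'   (pointwise max), intersection `z` (or `NA`), `case` (`"intersection"`,
#'   `"f1_only"`, `"f2_only"`).
#' @export
build_phase <- function(landscape, interval, boundary_values,
                        n_grid = 2001) {
  stopifnot(length(interval) == 2, interval[1] < interval[2],
            length(boundary_values) == 2)
  a_M <- max(global_maxima(landscape)$value)
  xs <- seq(interval[1], interval[2], length.out = n_grid)
  g <- sqrt(pmax(a_M - eval_landscape(landscape, xs, 0), 0))
  # cumulative integral from the left endpoint (trapezoid)
  h <- diff(xs)
  C <- c(0, cumsum((g[-1] + g[-length(g)]) / 2 * h))
  f1 <- boundary_values[1] - C
  f2 <- boundary_values[2] - (C[length(C)] - C)
  u <- pmax(f1, f2)
  dfs <- f1 - f2
  if (all(dfs >= 0)) {
    z <- NA_real_; case <- "f1_only"
  } else if (all(dfs <= 0)) {
    z <- NA_real_; case <- "f2_only"
  } else {
    iz <- which(diff(sign(dfs)) != 0)[1]
    # linear interpolation of the crossing
    z <- xs[iz] + (xs[iz + 1] - xs[iz]) * dfs[iz] / (dfs[iz] - dfs[iz + 1])
    case <- "intersection"
  }
  structure(list(x = xs, f1 = f1, f2 = f2, u = u, z = z, case = case,
                 a_M = a_M, interval = interval,
                 boundary_values = boundary_values),
            class = "phase_function")
}

#' Eikonal residual of a built phase
#'
#' Checks \eqn{||\partial_x u| - \sqrt{a_M - a}|} by centred differencing at
#' interior nodes away from the kink (branch intersection) and support edges.
#'
#' @param phase a `phase_function`.
#' @param landscape the landscape it was built from.
#' @param exclude half-width of the exclusion window around kinks.
#' @return Maximum absolute residual over the retained nodes.
#' @export
eikonal_residual <- function(phase, landscape, exclude = 0.05) {
  xs <- phase$x
  h <- xs[2] - xs[1]
  du <- abs(phase$u[-c(1, 2)] - phase$u[-c(length(xs) - 1, length(xs))]) /
    (2 * h)
  xm <- xs[-c(1, length(xs))]
  target <- sqrt(pmax(phase$a_M - eval_landscape(landscape, xm, 0), 0))
  kinks <- c(phase$z, unlist(lapply(landscape$components, function(b)
    c(b$center - b$half_width, b$center + b$half_width))))
  kinks <- kinks[is.finite(kinks)]
  keep <- rep(TRUE, length(xm))
  for (kk in kinks) keep <- keep & abs(xm - kk) > exclude
  max(abs(du[keep] - target[keep]))
}

#' Predict the concentration points of the rare-mutation limit
#'
#' Candidates are the lagged optima of all global maxima; the theory retains
#' those on the side where \eqn{a'(\bar x) > 0} for \eqn{c > 0} (mirrored for
#' \eqn{c < 0}), i.e. strictly behind the moving peaks, and the rescaled
#' eigenfunction concentrates only above peaks minimizing \eqn{|a''|} (the
#' shallowest-peak refinement). Tied minimal curvatures are all retained.
#'
#' @param landscape a validated Case-1 `fitness_landscape`.
#' @param c common shift speed.
#' @param curvature_tol tie tolerance on \eqn{|a''|}.
#' @return A `concentration_prediction` data frame: one row per candidate
#'   with `peak`, `curvature_magnitude`, `x_bar`, `lagged_fitness`,
#'   `selected`, `shallowest`.
#' @export
concentration_points <- function(landscape, c, curvature_tol = 1e-9) {
  peaks <- global_maxima(landscape)
  lo <- lagged_optima(landscape, c)
  if (nrow(lo) == 0)
    return(structure(data.frame(peak = numeric(0),
                                curvature_magnitude = numeric(0),
                                x_bar = numeric(0),
                                lagged_fitness = numeric(0),
                                selected = logical(0),
                                shallowest = logical(0)),
                     class = c("concentration_prediction", "data.frame")))
  curv <- peaks$curvature_magnitude[match(round(lo$peak, 9),
                                          round(peaks$location, 9))]
  selected <- if (c > 0) lo$slope > 0 else if (c < 0) lo$slope < 0
              else rep(TRUE, nrow(lo))
  cmin <- min(curv)
  shallow <- selected & (curv <= cmin + curvature_tol)
  out <- data.frame(peak = lo$peak, curvature_magnitude = curv,
                    x_bar = lo$x_bar, lagged_fitness = lo$lagged_fitness,
                    selected = selected, shallowest = shallow)
  structure(out, class = c("concentration_prediction", "data.frame"))
}
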