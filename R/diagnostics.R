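# Diagnostics connecting simulation to the spectral theory: co-moving
# re-framing, windowed mass fractions around candidate concentration points,
# and the limiting-mass identity rho_inf = integral(a p_eps) = -lambda_eps.

#' Re-frame a population state into co-moving coordinates
#'
#' Returns the state with density \eqn{N(x) = n(x + \epsilon c t)} by linear
#' re-interpolation onto the same grid (values translated off the domain are
#' zero; the shift must stay within half the domain).
#'
#' @param state a `population_state`.
#' @param c shift speed.
#' @param epsilon mutation scale.
#' @param t time of the shift (defaults to the state's own time).
#' @return A `population_state` in the co-moving frame.
#' @export
comoving <- function(state, c, epsilon, t = NULL) {
  t <- t %||% state$time
  grid <- state$grid
  shift <- epsilon * c * t
  if (abs(shift) > grid$L / 2)
    stop("co-moving shift exceeds half the domain; the window is out of ",
         "domain", call. = FALSE)
  if (shift == 0) return(state)
  dens <- stats::approx(grid$x, state$density, xout = grid$x + shift,
                        method = "linear", yleft = 0, yright = 0)$y
  dens[dens < 0] <- 0
  population_state(dens, grid, time = state$time)
}

#' Windowed mass fractions around candidate concentration points
#'
#' For each candidate \eqn{x_k}, the fraction of total mass within
#' \eqn{|x - x_k| \le w} (rectangle rule). The dominant candidate is the one
#' with fraction above `dominance`; ties and sub-threshold maxima are
#' undetermined. A state with \eqn{\rho} below `extinction_tol` is flagged
#' extinct instead.
#'
#' @param state a `population_state` (typically co-moving).
#' @param candidates candidate trait locations.
#' @param w window half-width; default \eqn{3\sqrt\epsilon} via the
#'   `epsilon` argument.
#' @param epsilon used only for the default window.
#' @param dominance dominance threshold (default 0.5).
#' @param extinction_tol mass threshold for the extinction flag.
#' @return A `concentration_report`: `time`, `rho`, `fractions`,
#'   `dominant` (index or `NA`), `argmax` (trait of the density maximum),
#'   `extinct`.
#' @export
locate_mass <- function(state, candidates, w = NULL, epsilon = NULL,
                        dominance = 0.5, extinction_tol = 1e-3) {
  stopifnot(length(candidates) >= 1)
  w <- w %||% (3 * sqrt(epsilon %||%
                          stop("supply `w` or `epsilon`", call. = FALSE)))
  grid <- state$grid
  if (state$rho < extinction_tol)
    return(structure(list(time = state$time, rho = state$rho,
                          fractions = rep(NA_real_, length(candidates)),
                          dominant = NA_integer_, argmax = NA_real_,
                          extinct = TRUE),
                     class = "concentration_report"))
  fr <- vapply(candidates, function(ck) {
    sel <- abs(grid$x - ck) <= w
    grid$dx * sum(state$density[sel]) / state$rho
  }, numeric(1))
  dom <- which.max(fr)
  if (fr[dom] <= dominance ||
      sum(abs(fr - fr[dom]) < 1e-12) > 1) dom <- NA_integer_
  structure(list(time = state$time, rho = state$rho, fractions = fr,
                 dominant = dom, argmax = grid$x[which.max(state$density)],
                 extinct = FALSE),
            class = "concentration_report")
}

#' Mass fractions along moving candidate tracks
#'
#' For lab-frame trajectories whose candidates move (Case 2: the lagged
#' optima tracks \eqn{\bar x_i + \epsilon c_i t}), evaluates the window
#' fraction around each track at every stored snapshot.
#'
#' @param traj an `fd_trajectory`.
#' @param tracks list of functions of `t` returning candidate locations.
#' @param w window half-width.
#' @return A data frame: `time`, `rho`, one `frac_k` column per track.
#' @export
track_fractions <- function(traj, tracks, w) {
  rows <- lapply(traj$snapshots, function(st) {
    fr <- vapply(tracks, function(trk) {
      ck <- trk(st$time)
      sel <- abs(st$grid$x - ck) <= w
      if (st$rho <= 0) return(NA_real_)
      st$grid$dx * sum(st$density[sel]) / st$rho
    }, numeric(1))
    c(time = st$time, rho = st$rho, stats::setNames(fr,
        paste0("frac_", seq_along(fr))))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Compare the simulated mass limit against the spectral prediction
#'
#' The total mass converges (when the population persists) to
#' \eqn{\rho_\infty = \int a\, p_\epsilon = -\lambda_\epsilon}. Compares the
#' tail-averaged \eqn{\rho(t)} against \eqn{-\lambda_\epsilon}, and reports
#' whether the tail is monotone (the eventually-monotonic behaviour seen in
#' the two-speed overlap experiment).
#'
#' @param times,rho the mass series.
#' @param lambda_eps the principal eigenvalue.
#' @param tail_fraction fraction of the series treated as the tail.
#' @param extinction_tol extinction threshold on the tail mean.
#' @return A list: `rho_tail`, `target` (\eqn{-\lambda}), `relative_gap`,
#'   `tail_monotone`, `extinct`, `stationary` (relative tail drift per unit
#'   time below 1e-6).
#' @export
rho_limit_check <- function(times, rho, lambda_eps, tail_fraction = 0.1,
                            extinction_tol = 1e-3) {
  n <- length(rho)
  stopifnot(length(times) == n, n >= 10)
  tail_idx <- seq.int(max(1L, ceiling(n * (1 - tail_fraction))), n)
  if (length(tail_idx) < 2) tail_idx <- (n - 1L):n
  rt <- mean(rho[tail_idx])
  if (rt < extinction_tol)
    return(list(rho_tail = rt, target = -lambda_eps, relative_gap = NA_real_,
                tail_monotone = NA, extinct = TRUE, stationary = NA))
  d <- diff(rho[tail_idx])
  mono <- all(d >= -1e-10 * rt) || all(d <= 1e-10 * rt)
  span <- times[tail_idx[length(tail_idx)]] - times[tail_idx[1]]
  drift <- abs(rho[tail_idx[length(tail_idx)]] - rho[tail_idx[1]]) /
    max(span, .Machine$double.eps) / rt
  list(rho_tail = rt, target = -lambda_eps,
       relative_gap = abs(rt + lambda_eps) / abs(lambda_eps),
       tail_monotone = mono, extinct = FALSE,
       stationary = drift < 1e-6)
}

#' Discrete mass identity for the drift eigenvector
#'
#' Integrating the drift eigenproblem over the ball gives
#' \eqn{\int a p_\epsilon = -\lambda_\epsilon} (boundary terms vanish with
#' the eigenvector's exponential decay). Evaluates the rectangle-rule left
#' side for an L1-normalized pair.
#'
#' @param pair an L1-normalized `eigen_pair` from
#'   [principal_eigenpair_drift()].
#' @param landscape the landscape it was built from.
#' @return A list: `integral` \eqn{= \Delta x \sum a_j p_j}, `target`
#'   \eqn{= -\lambda}, `abs_gap`.
#' @export
mass_identity_check <- function(pair, landscape) {
  if (pair$normalization != "L1_one")
    stop("mass identity requires an L1-normalized eigenvector", call. = FALSE)
  a_v <- eval_landscape(landscape, pair$x, 0)
  I <- pair$dx * sum(a_v * pair$vector)
  list(integral = I, target = -pair$lambda, abs_gap = abs(I + pair$lambda))
}
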