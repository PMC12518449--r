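# Asymptotic-preserving scheme for the constrained Hamilton-Jacobi
# formulation of the co-moving problem. With u = -eps log N the phase solves
#   du/dtau + |u_x - c/2|^2 = eps u_xx - (a(x) - c^2/4 - rho),
#   rho = integral exp(-u/eps),
# in the rescaled time tau = t/eps. The eps -> 0 limit scheme replaces rho
# by a multiplier P_n enforcing min_i v_i = 0 at every step.

#' Monotone numerical Hamiltonian
#'
#' \eqn{H(p, q) = \max\{H^+(p), H^-(q)\}} with \eqn{H^+(p) = p^2} for
#' \eqn{p > 0} (else 0) and \eqn{H^-(q) = q^2} for \eqn{q < 0} (else 0).
#' Nondecreasing in the backward slope `p`, nonincreasing in the forward
#' slope `q` (the monotone-scheme property).
#'
#' @param p backward difference-quotient(s), shifted by \eqn{-c/2}.
#' @param q forward difference-quotient(s), shifted by \eqn{-c/2}.
#' @return Elementwise numerical Hamiltonian.
#' @export
hamiltonian <- function(p, q) {
  pmax(ifelse(p > 0, p^2, 0), ifelse(q < 0, q^2, 0))
}

# slopes with one ghost node of linear extrapolation at each end
phase_slopes <- function(u, dx) {
  n <- length(u)
  ug <- c(2 * u[1] - u[2], u, 2 * u[n] - u[n - 1])
  list(back = (ug[2:(n + 1)] - ug[1:n]) / dx,
       fwd  = (ug[3:(n + 2)] - ug[2:(n + 1)]) / dx)
}

# sub-grid minimizer of a smooth phase: 3-point parabolic refinement of the
# discrete argmin (exact for locally quadratic phases)
phase_argmin <- function(u, x) {
  i <- which.min(u)
  n <- length(u)
  if (i == 1L || i == n) return(x[i])
  denom <- u[i - 1] - 2 * u[i] + u[i + 1]
  if (denom <= 0) return(x[i])
  off <- 0.5 * (u[i - 1] - u[i + 1]) / denom
  x[i] + max(-1, min(1, off)) * (x[2] - x[1])
}

# overflow-guarded mass dx * sum(exp(-u/eps))
phase_mass <- function(u, dx, epsilon) {
  e <- -u / epsilon
  m <- max(e)
  exp(m + log(dx) + log(sum(exp(e - m))))
}

#' Construct a Hamilton-Jacobi scheme state
#'
#' @param phase phase vector over the grid nodes (\eqn{\bar u} for
#'   \eqn{\epsilon > 0}, \eqn{v} for the limit scheme).
#' @param grid a `trait_grid`.
#' @param epsilon mutation scale, or `NULL` for the limit scheme.
#' @param mass total mass \eqn{\rho_n} (\eqn{\epsilon > 0}) or multiplier
#'   \eqn{P_n} (limit); recomputed from the phase when `NULL` for
#'   \eqn{\epsilon > 0}.
#' @return An `hj_state`.
#' @export
hj_state <- function(phase, grid, epsilon = NULL, mass = NULL) {
  stopifnot(length(phase) == grid$Nx)
  if (is.null(epsilon)) {
    if (abs(min(phase)) > 1e-10)
      stop("limit-scheme phase must satisfy min v = 0", call. = FALSE)
  } else if (is.null(mass)) {
    mass <- phase_mass(phase, grid$dx, epsilon)
  }
  structure(list(phase = phase, grid = grid, epsilon = epsilon, mass = mass),
            class = "hj_state")
}

#' One step of the eps > 0 asymptotic-preserving scheme
#'
#' \deqn{\bar u^{n+1}_i = \bar u^n_i - \Delta t\, H(D^-_i - c/2, D^+_i - c/2)
#'   + \Delta t\, \epsilon\, \Delta_h \bar u^n_i
#'   - \Delta t\, (a(x_i) - c^2/4 - \rho_n)}
#' with backward/forward difference quotients \eqn{D^\pm} and
#' \eqn{\rho_{n+1} = \Delta x \sum_i e^{-\bar u^{n+1}_i / \epsilon}}
#' (log-sum-exp guarded). The landscape is evaluated in the frozen frame.
#' `paper_literal = TRUE` reproduces the printed formula (forward slope
#' divided by \eqn{\Delta x^2}, diffusion divided by \eqn{\Delta x}).
#'
#' @param state an `hj_state` with `epsilon > 0`.
#' @param landscape a `fitness_landscape` (frozen frame).
#' @param dt time step (rescaled time).
#' @param c shift speed.
#' @param paper_literal reproduce the printed denominators.
#' @return The advanced `hj_state` (mass recomputed).
#' @export
hj_step_eps <- function(state, landscape, dt, c, paper_literal = FALSE) {
  if (is.null(state$epsilon)) stop("state has no epsilon; use hj_step_limit")
  grid <- state$grid; u <- state$phase; eps <- state$epsilon
  a <- eval_landscape(landscape, grid$x, 0)
  s <- phase_slopes(u, grid$dx)
  lap <- (s$fwd - s$back) / grid$dx  # (u_{i+1} - 2 u_i + u_{i-1}) / dx^2
  if (paper_literal) {
    H <- hamiltonian(s$back - c / 2, s$fwd / grid$dx - c / 2)
    diff_term <- eps * lap * grid$dx   # printed: second difference / dx
  } else {
    H <- hamiltonian(s$back - c / 2, s$fwd - c / 2)
    diff_term <- eps * lap
  }
  u_new <- u - dt * H + dt * diff_term - dt * (a - c^2 / 4 - state$mass)
  m <- phase_mass(u_new, grid$dx, eps)
  if (!is.finite(m))
    stop("mass overflow in the eps-scheme despite log-sum-exp guarding",
         call. = FALSE)
  hj_state(u_new, grid, epsilon = eps, mass = m)
}

#' Population-size multiplier of the limit scheme
#'
#' The pre-update \eqn{v^{n+1,\mathrm{pre}}_i(J) = v^n_i - \Delta t H_i -
#' \Delta t (a(x_i) - c^2/4 - J)} is affine and strictly increasing in `J`
#' with slope \eqn{+\Delta t} at every node, so
#' \eqn{J \mapsto \min_i v^{n+1,\mathrm{pre}}_i(J)} has the unique root
#' \deqn{P_{n+1} = \max_i\left[ a(x_i) - c^2/4 + H_i - v^n_i/\Delta t
#'   \right],}
#' returned in closed form (nodes at the phase minimum dominate; at
#' stationarity \eqn{P \to a_M - c^2/4}). `check_bisection = TRUE`
#' cross-checks by bracketed bisection to 1e-10.
#'
#' @param v current limit-scheme phase (min 0).
#' @param landscape a `fitness_landscape` (frozen frame).
#' @param grid a `trait_grid`.
#' @param dt time step.
#' @param c shift speed.
#' @param check_bisection also verify the root by bisection.
#' @return The multiplier \eqn{P_{n+1}} (scalar).
#' @export
hj_limit_multiplier <- function(v, landscape, grid, dt, c,
                                check_bisection = FALSE) {
  a <- eval_landscape(landscape, grid$x, 0)
  s <- phase_slopes(v, grid$dx)
  H <- hamiltonian(s$back - c / 2, s$fwd - c / 2)
  P <- max(a - c^2 / 4 + H - v / dt)
  if (check_bisection) {
    g <- function(J) min(v - dt * H - dt * (a - c^2 / 4 - J))
    lo <- min(a) - c^2 / 4 - 1; hi <- max(a) - c^2 / 4 + max(H) + 1
    # widen until bracketed (g is increasing)
    while (g(lo) > 0) lo <- lo - 1
    while (g(hi) < 0) hi <- hi + 1
    Pb <- stats::uniroot(g, lower = lo, upper = hi, tol = 1e-10)$root
    if (abs(Pb - P) > 1e-8)
      stop("closed-form multiplier disagrees with bisection", call. = FALSE)
  }
  P
}

#' One step of the eps = 0 limit scheme
#'
#' Applies the limit-scheme update with the multiplier from
#' [hj_limit_multiplier()]; the post-state satisfies
#' \eqn{\min_i v^{n+1}_i = 0} to machine precision (asserted to 1e-10).
#'
#' @inheritParams hj_step_eps
#' @param state an `hj_state` with `epsilon = NULL` (mass slot holds
#'   \eqn{P_n}).
#' @return The advanced `hj_state` with `mass` = \eqn{P_{n+1}}.
#' @export
hj_step_limit <- function(state, landscape, dt, c) {
  grid <- state$grid; v <- state$phase
  if (min(v) < -1e-10 || min(v) > 1e-10)
    stop("limit-scheme precondition min v = 0 violated", call. = FALSE)
  a <- eval_landscape(landscape, grid$x, 0)
  s <- phase_slopes(v, grid$dx)
  H <- hamiltonian(s$back - c / 2, s$fwd - c / 2)
  P <- max(a - c^2 / 4 + H - v / dt)
  v_new <- v - dt * H - dt * (a - c^2 / 4 - P)
  if (abs(min(v_new)) > 1e-10)
    stop("limit-scheme constraint min v = 0 violated beyond 1e-10",
         call. = FALSE)
  v_new <- v_new - min(v_new)  # remove the O(eps_machine) rounding residue
  hj_state(v_new, grid, epsilon = NULL, mass = P)
}

#' Run a Hamilton-Jacobi scheme
#'
#' Integrates either the \eqn{\epsilon > 0} scheme or the limit scheme to
#' rescaled time `T` on a frozen landscape.
#'
#' @param landscape a `fitness_landscape`.
#' @param u0 initial phase: function of `x` or vector over the grid. For the
#'   limit scheme the minimum is subtracted so that `min v = 0` exactly.
#' @param grid a `trait_grid`.
#' @param T rescaled-time horizon.
#' @param c shift speed (defaults to the landscape's common speed).
#' @param epsilon mutation scale, or `NULL` for the limit scheme.
#' @param dt time step. The default respects the gradient CFL for the slope
#'   bound the phase approaches at stationarity,
#'   \eqn{S = \sqrt{a_M - a_m} + |c|/2} (the eikonal slope plus the drift
#'   offset), not just the initial slopes: `dt = dx / (4 (S + 1))`, further
#'   capped by the diffusion bound `0.2 dx^2 / epsilon` for the
#'   \eqn{\epsilon > 0} scheme.
#' @return An `hj_trajectory`: `times`, `mass` series (\eqn{\rho_n} or
#'   \eqn{P_n}), final `state`, `argmin` track (trait location of the phase
#'   minimum at every step).
#' @export
hj_run <- function(landscape, u0, grid, T, c = NULL, epsilon = NULL,
                   dt = NULL) {
  c <- c %||% landscape$components[[1]]$shift_speed
  if (is.null(dt)) {
    av <- eval_landscape(landscape, grid$x, 0)
    S <- sqrt(max(av) - min(av)) + abs(c) / 2
    dt <- grid$dx / (4 * (S + 1))
    if (!is.null(epsilon)) dt <- min(dt, 0.2 * grid$dx^2 / epsilon)
  }
  phase0 <- if (is.function(u0)) u0(grid$x) else u0
  if (is.null(epsilon)) phase0 <- phase0 - min(phase0)
  state <- hj_state(phase0, grid, epsilon = epsilon,
                    mass = if (is.null(epsilon))
                      NA_real_ else NULL)
  Nt <- ceiling(T / dt); dt <- T / Nt
  times <- numeric(Nt + 1); mass <- numeric(Nt + 1); amin <- numeric(Nt + 1)
  times[1] <- 0
  mass[1] <- if (is.null(epsilon)) NA_real_ else state$mass
  amin[1] <- phase_argmin(state$phase, grid$x)
  for (k in seq_len(Nt)) {
    state <- if (is.null(epsilon)) hj_step_limit(state, landscape, dt, c)
             else hj_step_eps(state, landscape, dt, c)
    times[k + 1] <- k * dt
    mass[k + 1] <- state$mass
    amin[k + 1] <- phase_argmin(state$phase, grid$x)
  }
  structure(list(times = times, mass = mass, argmin = amin, state = state,
                 grid = grid, epsilon = epsilon, c = c, dt = dt),
            class = "hj_trajectory")
}
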