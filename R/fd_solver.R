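# Explicit finite-difference solver for the non-local selection-mutation PDE
#   dn/dt - eps^2 n_xx = n (a(x, t) - rho(t)),   rho = integral of n,
# on the truncated trait domain [0, L] with homogeneous Dirichlet rows.

#' Trait and time grids
#'
#' The trait domain is \eqn{[0, L]} discretized as \eqn{x_j = j \Delta x},
#' \eqn{j = 1, \dots, N_x}, with the boundary rows \eqn{j = 1} and
#' \eqn{j = N_x} held at zero.
#'
#' @param L domain length.
#' @param Nx node count.
#' @return A `trait_grid` with fields `L`, `Nx`, `dx`, `x`.
#' @export
trait_grid <- function(L, Nx) {
  stopifnot(L > 0, Nx >= 8)
  dx <- L / Nx
  structure(list(L = L, Nx = as.integer(Nx), dx = dx, x = (1:Nx) * dx),
            class = "trait_grid")
}

#' @rdname trait_grid
#' @param T time horizon.
#' @param Nt step count (`dt * Nt = T`).
#' @export
time_grid <- function(T, Nt) {
  stopifnot(T > 0, Nt >= 1)
  structure(list(T = T, Nt = as.integer(Nt), dt = T / Nt),
            class = "time_grid")
}

#' Largest stable explicit time step
#'
#' The diffusion-stability (CFL) bound for the forward-Euler
#' centre-difference scheme: \eqn{\Delta t \le \Delta x^2 / (2\epsilon^2)},
#' scaled by a safety factor.
#'
#' @param grid a `trait_grid`.
#' @param epsilon mutation scale.
#' @param safety safety factor in (0, 1], default 0.9.
#' @return The largest admitted `dt`.
#' @export
cfl_bound <- function(grid, epsilon, safety = 0.9) {
  stopifnot(epsilon > 0, safety > 0, safety <= 1)
  safety * grid$dx^2 / (2 * epsilon^2)
}

#' Construct a population state
#'
#' @param density nonnegative density vector over the grid nodes
#'   (individuals per unit trait); boundary entries forced to zero.
#' @param grid a `trait_grid`.
#' @param time time stamp.
#' @return A `population_state` with total mass `rho` (rectangle rule).
#' @export
population_state <- function(density, grid, time = 0) {
  stopifnot(length(density) == grid$Nx)
  if (any(density < 0))
    stop("density must be nonnegative", call. = FALSE)
  density[c(1L, grid$Nx)] <- 0
  structure(list(density = density, time = time, grid = grid,
                 rho = grid$dx * sum(density)),
            class = "population_state")
}

#' One forward-Euler step of the non-local PDE
#'
#' In `"corrected"` mode (the full model):
#' \deqn{n^{k+1}_j = n^k_j + \frac{\epsilon^2 \Delta t}{\Delta x^2}
#'   (n^k_{j+1} - 2 n^k_j + n^k_{j-1})
#'   + \Delta t\, n^k_j (a(x_j, t_{k+1}) - \rho^k)}
#' with \eqn{\rho^k} from the incoming state. `"paper_literal"` applies the
#' printed update verbatim: no \eqn{\epsilon^2} factor on the diffusion term
#' and the growth term \eqn{a(x_j, t_{k+1})} used as-is (any competition must
#' be folded into `a` by the caller).
#'
#' @param state a `population_state`.
#' @param landscape a `fitness_landscape`.
#' @param dt time step; `"corrected"` mode enforces [cfl_bound()].
#' @param epsilon mutation scale.
#' @param mode `"corrected"` (default) or `"paper_literal"`.
#' @return The advanced `population_state`.
#' @export
step_explicit <- function(state, landscape, dt, epsilon,
                          mode = c("corrected", "paper_literal")) {
  mode <- match.arg(mode)
  grid <- state$grid
  n <- state$density
  Nx <- grid$Nx
  t_next <- state$time + dt
  a_next <- eval_landscape(landscape, grid$x, t_next)
  j <- 2:(Nx - 1)
  lap <- n[j + 1] - 2 * n[j] + n[j - 1]
  if (mode == "corrected") {
    if (dt > cfl_bound(grid, epsilon, safety = 1) + 1e-12)
      stop("dt exceeds the diffusion CFL bound dx^2/(2 eps^2)", call. = FALSE)
    new <- n
    new[j] <- n[j] + (epsilon^2 * dt / grid$dx^2) * lap +
      dt * n[j] * (a_next[j] - state$rho)
  } else {
    new <- n
    new[j] <- n[j] + (dt / grid$dx^2) * lap + dt * n[j] * a_next[j]
  }
  new[c(1L, Nx)] <- 0
  if (any(!is.finite(new)))
    stop("non-finite density: explicit step unstable (check the CFL bound)",
         call. = FALSE)
  if (any(new < 0)) {
    if (min(new) < -1e-8 * max(abs(new)))
      stop("negative density overflow: explicit step unstable ",
           "(check the CFL bound)", call. = FALSE)
    new[new < 0] <- 0
  }
  population_state(new, grid, time = t_next)
}

#' Run the finite-difference simulation
#'
#' Integrates the non-local PDE from `n0` to time `T`. `frame = "lab"` keeps
#' the landscape shifting at \eqn{\epsilon c t}; `frame = "comoving"` freezes
#' the landscape and adds the upwind-discretized drift term
#' \eqn{\epsilon c \partial_x N} of the co-moving formulation (Case 1 only).
#'
#' @param landscape a `fitness_landscape`.
#' @param n0 initial density: a function of `x` or a vector over the grid.
#' @param grid a `trait_grid`.
#' @param T time horizon (the PDE's own time).
#' @param dt time step; default `min(cfl_bound(grid, epsilon), 0.05)`.
#' @param epsilon mutation scale (defaults to the landscape's).
#' @param mode passed to [step_explicit()].
#' @param frame `"lab"` or `"comoving"`.
#' @param snapshot_stride store a snapshot every this many steps.
#' @param boundary_margin required distance between the (shifted) landscape
#'   support and the domain boundary for all `t <= T`.
#' @return A `fd_trajectory`: list with `times` (all step times), `rho`
#'   (mass series), `snapshots` (list of `population_state`), `grid`,
#'   `epsilon`, `mode`, `frame`.
#' @export
fd_run <- function(landscape, n0, grid, T, dt = NULL, epsilon = NULL,
                   mode = "corrected", frame = c("lab", "comoving"),
                   snapshot_stride = 100, boundary_margin = 5) {
  frame <- match.arg(frame)
  epsilon <- epsilon %||% landscape$epsilon
  dt <- dt %||% min(cfl_bound(grid, epsilon), 0.05)
  speeds <- if (is.null(landscape$custom_fun))
    vapply(landscape$components, `[[`, numeric(1), "shift_speed")
  else landscape$shift_speed
  if (frame == "lab") {
    for (tt in c(0, T)) {
      if (is.null(landscape$custom_fun)) {
        lo_t <- min(vapply(landscape$components, function(b)
          b$center - b$half_width + epsilon * b$shift_speed * tt, numeric(1)))
        hi_t <- max(vapply(landscape$components, function(b)
          b$center + b$half_width + epsilon * b$shift_speed * tt, numeric(1)))
      } else {
        lo_t <- landscape$support_lo + epsilon * speeds * tt
        hi_t <- landscape$support_hi + epsilon * speeds * tt
      }
      if (lo_t < grid$x[1] + boundary_margin ||
          hi_t > grid$L - boundary_margin)
        stop("shifted landscape support comes within ", boundary_margin,
             " trait units of the domain boundary before T; enlarge the ",
             "domain or shorten the run", call. = FALSE)
    }
  } else {
    if (landscape$case_tag != "case1_common_speed")
      stop("comoving frame requires a common shift speed (Case 1)",
           call. = FALSE)
  }
  cc <- speeds[1]
  dens0 <- if (is.function(n0)) n0(grid$x) else n0
  state <- population_state(dens0, grid, time = 0)
  Nt <- ceiling(T / dt)
  dt <- T / Nt
  times <- numeric(Nt + 1); rho <- numeric(Nt + 1)
  times[1] <- 0; rho[1] <- state$rho
  snapshots <- list(state)
  a_frozen <- if (frame == "comoving") eval_landscape(landscape, grid$x, 0)
  j <- 2:(grid$Nx - 1)
  for (k in seq_len(Nt)) {
    if (frame == "lab") {
      state <- step_explicit(state, landscape, dt, epsilon, mode)
    } else {
      n <- state$density
      lap <- n[j + 1] - 2 * n[j] + n[j - 1]
      # upwind drift for dN/dt = ... + eps*c*dN/dx (information moves left
      # for c > 0, so use the forward difference there)
      drift <- if (cc >= 0) (n[j + 1] - n[j]) / grid$dx
               else (n[j] - n[j - 1]) / grid$dx
      new <- n
      new[j] <- n[j] + (epsilon^2 * dt / grid$dx^2) * lap +
        dt * epsilon * cc * drift +
        dt * n[j] * (a_frozen[j] - state$rho)
      new[c(1L, grid$Nx)] <- 0
      new[new < 0 & new > -1e-12] <- 0
      state <- population_state(new, grid, time = state$time + dt)
    }
    times[k + 1] <- state$time
    rho[k + 1] <- state$rho
    if (k %% snapshot_stride == 0 || k == Nt)
      snapshots[[length(snapshots) + 1L]] <- state
  }
  structure(list(times = times, rho = rho, snapshots = snapshots,
                 grid = grid, epsilon = epsilon, mode = mode, frame = frame,
                 landscape = landscape, c = cc, dt = dt),
            class = "fd_trajectory")
}

#' Write a mass series as a plain-text table
#'
#' @param traj a `fd_trajectory` (or any list with `times` and `rho`).
#' @param path output path; a headered two-column CSV `time,rho`.
#' @export
write_mass_series <- function(traj, path) {
  utils::write.csv(data.frame(time = traj$times, rho = traj$rho),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
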