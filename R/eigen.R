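# Principal-eigenvalue machinery for the stationary problems on Dirichlet
# balls: -eps^2 p'' - V(x) p = lambda p on (center - R, center + R), p = 0 at
# the endpoints, with V the effective potential (a - c^2/4, or
# a_i - c_i^2/4 - d in the two-speed case). The principal pair is computed by
# shifted inverse iteration on the interior tridiagonal operator; the drift
# problem is handled by the discrete Liouville similarity (exact spectral
# equivalence) or by a direct nonsymmetric solve as a cross-check.

#' Specify a discretized Dirichlet eigenproblem
#'
#' @param potential effective potential: a function of `x` or a
#'   `fitness_landscape` (then \eqn{V = a(\cdot, 0) - c^2/4} with `c` taken
#'   from `drift`).
#' @param epsilon mutation scale.
#' @param R ball radius.
#' @param center ball center; defaults to the mean peak location for a
#'   landscape potential, else 0. All radii sharing one center give nested
#'   domains (monotone eigenvalues).
#' @param dx grid spacing; default `epsilon / 10` so the \eqn{O(\sqrt\epsilon)}
#'   eigenvector width is resolved.
#' @param drift drift speed c (0 for the transformed symmetric problems).
#' @return An `eigen_spec`.
#' @export
eigen_spec <- function(potential, epsilon, R, center = NULL, dx = NULL,
                       drift = 0) {
  stopifnot(epsilon > 0, R > 0)
  if (inherits(potential, "fitness_landscape")) {
    center <- center %||% mean(vapply(potential$components, `[[`,
                                      numeric(1), "center"))
    ls <- potential
    cc <- drift
    potential <- function(x) eval_landscape(ls, x, 0) - cc^2 / 4
    drift <- 0  # the c^2/4 shift absorbs the drift (Liouville transform)
  } else {
    stopifnot(is.function(potential))
    center <- center %||% 0
  }
  dx <- dx %||% (epsilon / 10)
  structure(list(potential = potential, epsilon = epsilon, R = R,
                 center = center, dx = dx, drift = drift),
            class = "eigen_spec")
}

# interior nodes of the ball
spec_nodes <- function(spec) {
  n_cells <- max(8L, round(2 * spec$R / spec$dx))
  dx <- 2 * spec$R / n_cells
  list(x = spec$center - spec$R + dx * seq_len(n_cells - 1L), dx = dx)
}

# Shifted inverse iteration for the algebraically smallest eigenvalue of a
# tridiagonal operator with positive principal eigenvector. `lower` must be a
# strict lower bound on the principal eigenvalue, and should be close to it
# (the linear convergence rate is (lambda1 - lower)/(lambda2 - lower)): the
# callers use the Rayleigh bound lambda >= -max(potential) minus a margin.
# Once nearly converged the shift moves to the Rayleigh quotient minus the
# residual, which stays below lambda1 (RQ - lambda1 <= res^2/gap <= res near
# convergence) and gives cubic convergence.
tridiag_principal <- function(diag_main, off_lower, off_upper, lower,
                              tol = 1e-13, max_iter = 600) {
  n <- length(diag_main)
  A <- Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                          diagonals = list(off_lower, diag_main, off_upper))
  scale <- max(1, max(abs(diag_main)))
  v <- rep(1 / sqrt(n), n)
  sigma <- lower
  lam <- NA_real_
  res <- Inf
  I <- Matrix::Diagonal(n)
  M <- A - sigma * I
  for (it in seq_len(max_iter)) {
    w <- as.numeric(Matrix::solve(M, v))
    w <- w / sqrt(sum(w^2))
    Aw <- as.numeric(A %*% w)
    lam_new <- sum(w * Aw)
    res <- sqrt(sum((Aw - lam_new * w)^2))
    v <- w
    lam <- lam_new
    if (res <= tol * scale) break
    if (res < 1e-4) {
      sigma_new <- lam_new - max(res, 1e-14)
      if (is.finite(sigma_new) && sigma_new > sigma) {
        sigma <- sigma_new
        M <- A - sigma * I
      }
    }
  }
  if (res > 1e-8 * scale)
    stop("inverse iteration did not converge (residual ", signif(res, 3), ")",
         call. = FALSE)
  if (sum(v) < 0) v <- -v
  if (min(v) < -1e-8 * max(v))
    stop("computed principal eigenvector changes sign (numerical failure)",
         call. = FALSE)
  v[v < 0] <- 0
  list(lambda = lam, vector = v, residual = res)
}

#' Principal eigenpair of the symmetric Dirichlet problem
#'
#' Builds the interior tridiagonal operator
#' \eqn{-\epsilon^2 \Delta_h - \mathrm{diag}(V)} with zero Dirichlet rows and
#' returns its smallest eigenvalue with the (strictly positive, Perron)
#' eigenvector.
#'
#' @param spec an `eigen_spec` with `drift = 0`.
#' @param normalization `"L1_one"` (\eqn{\Delta x \sum p = 1}) or
#'   `"sup_one"` (\eqn{\max p = 1}).
#' @return An `eigen_pair`: `lambda`, `vector`, `x`, `dx`, `normalization`,
#'   `provenance`, `epsilon`, `R`, `center`.
#' @export
principal_eigenpair_dirichlet <- function(spec,
                                          normalization = c("L1_one",
                                                            "sup_one")) {
  normalization <- match.arg(normalization)
  if (spec$drift != 0)
    stop("symmetric solver requires drift = 0; use principal_eigenpair_drift",
         call. = FALSE)
  nd <- spec_nodes(spec)
  V <- spec$potential(nd$x)
  eps <- spec$epsilon
  k <- eps^2 / nd$dx^2
  res <- tridiag_principal(2 * k - V,
                           rep(-k, length(nd$x) - 1L),
                           rep(-k, length(nd$x) - 1L),
                           lower = -max(V) - 0.5)
  p <- normalize_vec(res$vector, nd$dx, normalization)
  structure(list(lambda = res$lambda, vector = p, x = nd$x, dx = nd$dx,
                 normalization = normalization, provenance = "dirichlet_ball",
                 epsilon = eps, R = spec$R, center = spec$center),
            class = "eigen_pair")
}

normalize_vec <- function(v, dx, normalization) {
  if (normalization == "L1_one") v / (dx * sum(v)) else v / max(v)
}

#' Principal eigenpair of the drift problem
#'
#' Solves \eqn{-\epsilon^2 p'' - \epsilon c\, p' - a(x) p = \lambda p} on the
#' ball with Dirichlet ends. `method = "similarity"` solves the symmetric
#' problem for \eqn{a - c^2/4} and maps the eigenvector through the discrete
#' Liouville weight \eqn{e^{-c (x - x_{\max})/(2\epsilon)}} (in log space, so
#' tails underflow gracefully); the eigenvalue is unchanged exactly.
#' `method = "direct"` discretizes the drift with centred differences and
#' runs shifted inverse iteration on the nonsymmetric tridiagonal operator
#' (real spectrum for \eqn{\Delta x < 2\epsilon/c}).
#'
#' @param landscape a `fitness_landscape` (frozen frame) or a function `a(x)`.
#' @param c drift speed.
#' @param epsilon mutation scale.
#' @param R ball radius.
#' @param center ball center (default: mean peak location / 0 as in
#'   [eigen_spec()]).
#' @param dx grid spacing (default `epsilon/10`).
#' @param method `"similarity"` (default) or `"direct"`.
#' @param normalization as in [principal_eigenpair_dirichlet()].
#' @return An `eigen_pair` with provenance `"drift_via_similarity"` or
#'   `"drift_direct"`.
#' @export
principal_eigenpair_drift <- function(landscape, c, epsilon, R,
                                      center = NULL, dx = NULL,
                                      method = c("similarity", "direct"),
                                      normalization = c("L1_one",
                                                        "sup_one")) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  if (inherits(landscape, "fitness_landscape")) {
    center <- center %||% mean(vapply(landscape$components, `[[`,
                                      numeric(1), "center"))
    ls <- landscape
    a_fun <- function(x) eval_landscape(ls, x, 0)
  } else {
    stopifnot(is.function(landscape))
    a_fun <- landscape
    center <- center %||% 0
  }
  if (method == "similarity") {
    spec <- eigen_spec(function(x) a_fun(x) - c^2 / 4, epsilon, R,
                       center = center, dx = dx)
    sym <- principal_eigenpair_dirichlet(spec, normalization = "sup_one")
    # the iterative solver leaves a ~1e-16-relative noise floor in the far
    # tails, which the exponential Liouville weight would amplify; re-solve
    # the tails from the converged eigenvalue first
    log_phat <- refine_sym_log_tails(
      ifelse(sym$vector > 0, log(sym$vector), -Inf),
      sym$x, sym$dx, epsilon, spec$potential(sym$x), sym$lambda)
    # log-space Liouville map: log p = -c (x - x_ref) / (2 eps) + log p_hat
    x_ref <- sym$x[which.max(log_phat)]
    logp <- -c * (sym$x - x_ref) / (2 * epsilon) + log_phat
    logp <- logp - max(logp)
    p <- exp(logp)
    p <- normalize_vec(p, sym$dx, normalization)
    structure(list(lambda = sym$lambda, vector = p, x = sym$x, dx = sym$dx,
                   normalization = normalization,
                   provenance = "drift_via_similarity",
                   epsilon = epsilon, R = R, center = center,
                   symmetric_lambda = sym$lambda),
              class = "eigen_pair")
  } else {
    spec <- eigen_spec(a_fun, epsilon, R, center = center, dx = dx)
    nd <- spec_nodes(spec)
    if (nd$dx >= 2 * epsilon / max(abs(c), 1e-300))
      stop("direct drift discretization needs dx < 2 eps / |c| for a real ",
           "principal eigenvalue", call. = FALSE)
    a_v <- a_fun(nd$x)
    k <- epsilon^2 / nd$dx^2
    m <- epsilon * c / (2 * nd$dx)
    n <- length(nd$x)
    res <- tridiag_principal(2 * k - a_v,
                             rep(-k + m, n - 1L),   # coefficient of p_{j-1}
                             rep(-k - m, n - 1L),   # coefficient of p_{j+1}
                             lower = -max(a_v) - c^2 / 4 - 0.6)
    p <- normalize_vec(res$vector, nd$dx, normalization)
    structure(list(lambda = res$lambda, vector = p, x = nd$x, dx = nd$dx,
                   normalization = normalization, provenance = "drift_direct",
                   epsilon = epsilon, R = R, center = center),
              class = "eigen_pair")
  }
}

#' Eigenvalue as a function of the ball radius
#'
#' \eqn{\lambda_{R,\epsilon}} is monotonically nonincreasing in `R` (nested
#' Rayleigh quotients); the sequence stabilizes once the eigenvector's
#' exponential tails are contained, which justifies using the largest-radius
#' value as the whole-line eigenvalue.
#'
#' @param potential function of `x` (effective potential).
#' @param epsilon mutation scale.
#' @param radii increasing radii.
#' @param center shared ball center.
#' @param dx shared grid spacing.
#' @param tol allowed monotonicity violation (discretization slack).
#' @return A data frame `(R, lambda)`.
#' @export
lambda_R_curve <- function(potential, epsilon, radii, center = 0,
                           dx = NULL, tol = 1e-10) {
  stopifnot(all(diff(radii) > 0))
  lam <- vapply(radii, function(R) {
    principal_eigenpair_dirichlet(
      eigen_spec(potential, epsilon, R, center = center, dx = dx))$lambda
  }, numeric(1))
  if (any(diff(lam) > tol))
    stop("lambda(R) not nonincreasing beyond tolerance; refine the grid",
         call. = FALSE)
  data.frame(R = radii, lambda = lam)
}

#' Whole-line eigenvalue by radius stabilization
#'
#' Doubles the radius until \eqn{|\lambda_{2R} - \lambda_R|} falls below
#' `stab_tol` and returns the last pair.
#'
#' @inheritParams lambda_R_curve
#' @param R0 starting radius.
#' @param stab_tol stabilization threshold.
#' @return An `eigen_pair` with provenance `"whole_line_extrapolated"`.
#' @export
principal_eigenpair_wholeline <- function(potential, epsilon, R0 = 10,
                                          center = 0, dx = NULL,
                                          stab_tol = 1e-8, max_doublings = 5) {
  R <- R0
  prev <- principal_eigenpair_dirichlet(
    eigen_spec(potential, epsilon, R, center = center, dx = dx))
  for (i in seq_len(max_doublings)) {
    R <- 2 * R
    cur <- principal_eigenpair_dirichlet(
      eigen_spec(potential, epsilon, R, center = center, dx = dx))
    if (abs(cur$lambda - prev$lambda) < stab_tol) {
      cur$provenance <- "whole_line_extrapolated"
      return(cur)
    }
    prev <- cur
  }
  warning("eigenvalue did not stabilize to ", stab_tol,
          " within the radius budget", call. = FALSE)
  prev$provenance <- "whole_line_extrapolated"
  prev
}

#' Small-mutation limit of the eigenvalue
#'
#' Tabulates \eqn{\lambda_\epsilon} against the limiting value
#' \eqn{-(a_M - c^2/4)} over a decreasing sequence of \eqn{\epsilon}. The gap
#' \eqn{\lambda_\epsilon + (a_M - c^2/4)} is positive (Rayleigh bound) and
#' shrinks like the harmonic ground-state correction
#' \eqn{\epsilon \sqrt{|a''|/2}} at a quadratic peak.
#'
#' @param landscape a `fitness_landscape`.
#' @param c drift speed.
#' @param epsilons decreasing mutation scales.
#' @param R ball radius.
#' @param center ball center (default: mean peak location).
#' @return A data frame `(epsilon, lambda, gap)` with attribute
#'   `limit_value` \eqn{= -(a_M - c^2/4)}.
#' @export
epsilon_limit_check <- function(landscape, c, epsilons, R, center = NULL) {
  stopifnot(all(diff(epsilons) < 0))
  peaks <- global_maxima(landscape)
  a_M <- max(peaks$value)
  limit <- -(a_M - c^2 / 4)
  rows <- lapply(epsilons, function(eps) {
    pair <- principal_eigenpair_dirichlet(
      eigen_spec(landscape, eps, R, center = center, drift = c))
    data.frame(epsilon = eps, lambda = pair$lambda,
               gap = pair$lambda - limit)
  })
  out <- do.call(rbind, rows)
  if (any(out$gap <= 0))
    stop("gap not positive: eigenvalue below the Rayleigh bound ",
         "(resolution failure)", call. = FALSE)
  if (any(diff(out$gap) >= 0))
    stop("gap not decreasing in epsilon (resolution failure)", call. = FALSE)
  attr(out, "limit_value") <- limit
  out
}

#' Check the pointwise decay envelopes of the drift eigenvector
#'
#' Verifies, on the sup-normalized drift eigenvector, the bounds
#' \deqn{e^{-\underline\kappa |x - x_\epsilon| / \epsilon} \le p(x) \le
#'   \min\{1, e^{-\overline\kappa (|x| - R_0)/\epsilon}\}}
#' for \eqn{|x| > R_0 + 1}, with
#' \eqn{\overline\kappa = (\sqrt{a_M} + c)/2} and
#' \eqn{\underline\kappa = c/2 + 2\sqrt{|a_m + \lambda_\epsilon - c^2/4|}}
#' evaluated from the computed eigenvalue. \eqn{R_0} is the outer edge of the
#' landscape support in the original coordinates. Because inverse iteration
#' leaves a relative noise floor far above the true exponential tail, the
#' tails are first re-solved from the converged eigenvalue on the tail
#' subdomain (anchored boundary-value solve). Nodes within 2 trait units of
#' the ball edge and underflowed nodes are excluded; the comparison allows a
#' 5% slack on the log scale.
#'
#' @param pair a sup-normalized `eigen_pair` from
#'   [principal_eigenpair_drift()].
#' @param landscape the `fitness_landscape` used to build it.
#' @param c drift speed.
#' @return A list: `n_checked`, `n_upper_violations`, `n_lower_violations`,
#'   `worst_upper_margin`, `worst_lower_margin` (log-scale margins; positive
#'   means satisfied), `kappa_bar`, `kappa_underbar`.
#' @export
decay_envelope_check <- function(pair, landscape, c) {
  if (pair$normalization != "sup_one")
    stop("envelope check requires a sup-normalized eigenvector",
         call. = FALSE)
  eps <- pair$epsilon
  peaks <- global_maxima(landscape)
  a_M_raw <- max(peaks$value) + landscape$d  # max of the bump sum, before -d
  a_m <- min(eval_landscape(landscape,
                            seq(pair$x[1], pair$x[length(pair$x)],
                                length.out = 2001), 0))
  R0 <- max(abs(c(landscape$support_lo, landscape$support_hi)))
  kbar <- (sqrt(max(a_M_raw, 0)) + c) / 2
  kund <- c / 2 + 2 * sqrt(abs(a_m + pair$lambda - c^2 / 4))
  if (pair$provenance != "drift_via_similarity")
    stop("envelope check needs a similarity-mapped pair (refined tails)",
         call. = FALSE)
  logp <- ifelse(pair$vector > 0, log(pair$vector), -Inf)
  x <- pair$x
  x_eps <- x[which.max(pair$vector)]
  sel <- abs(x) > R0 + 1 &
    x > x[1] + 2 & x < x[length(x)] - 2 &
    is.finite(logp)
  log_upper <- pmin(0, -kbar * (abs(x) - R0) / eps)
  log_lower <- -kund * abs(x - x_eps) / eps
  up_margin <- log_upper[sel] - logp[sel]
  lo_margin <- logp[sel] - log_lower[sel]
  slack_up <- 0.05 * pmax(abs(log_upper[sel]), 1)
  slack_lo <- 0.05 * pmax(abs(log_lower[sel]), 1)
  list(n_checked = sum(sel),
       n_upper_violations = sum(up_margin < -slack_up),
       n_lower_violations = sum(lo_margin < -slack_lo),
       worst_upper_margin = if (any(sel)) min(up_margin) else NA_real_,
       worst_lower_margin = if (any(sel)) min(lo_margin) else NA_real_,
       kappa_bar = kbar, kappa_underbar = kund)
}

# Re-solve the tails of a symmetric Dirichlet eigenvector from its converged
# eigenvalue: on each tail subdomain (beyond the last node where p exceeds
# anchor_frac of its max) the interior rows of (A - lambda I) p = 0 form a
# well-conditioned tridiagonal boundary-value problem with the anchor value
# and the Dirichlet zero as boundary data. Returns the refined log p (sup-
# normalized); nodes that underflow stay -Inf.
refine_sym_log_tails <- function(log_phat, x, dx, eps, V, lam_hat,
                                 anchor_frac = 1e-8) {
  log_phat <- log_phat - max(log_phat, na.rm = TRUE)
  n <- length(x)
  k <- eps^2 / dx^2
  diag_main <- 2 * k - V - lam_hat
  solve_tail <- function(idx_anchor, side) {
    # rows strictly between the anchor node and the Dirichlet ball edge
    # (which lies one step beyond node 1 / node n, value 0); the anchor
    # value is scaled to 1, so the solve is well-conditioned, and the log
    # anchor value is added back afterwards
    rng <- if (side == "right") seq(idx_anchor + 1L, n)
           else seq(1L, idx_anchor - 1L)
    if (length(rng) < 2) return(NULL)
    m <- length(rng)
    A <- Matrix::bandSparse(m, m, k = c(-1, 0, 1),
                            diagonals = list(rep(-k, m - 1),
                                             diag_main[rng],
                                             rep(-k, m - 1)))
    rhs <- numeric(m)
    if (side == "right") rhs[1] <- k else rhs[m] <- k
    sol <- as.numeric(Matrix::solve(A, rhs))
    sol[sol <= 0] <- NA_real_
    list(rng = rng, logv = log(sol) + log_phat[idx_anchor])
  }
  mx <- max(log_phat)
  good <- which(log_phat > mx + log(anchor_frac))
  iL <- min(good); iR <- max(good)
  out <- log_phat
  if (iL > 2) {
    tl <- solve_tail(iL, "left")
    if (!is.null(tl)) out[tl$rng] <- tl$logv
  }
  if (iR < n - 1) {
    tr <- solve_tail(iR, "right")
    if (!is.null(tr)) out[tr$rng] <- tr$logv
  }
  out[is.na(out)] <- -Inf
  out - max(out, na.rm = TRUE)
}

#' Classify persistence in the two-speed (diverging-optima) case
#'
#' Computes, for each component group \eqn{i}, the principal eigenvalue
#' \eqn{\lambda_{i,\epsilon}} of the symmetric problem with potential
#' \eqn{a_i(x) - c_i^2/4 - d}. The population goes extinct iff
#' \eqn{\min(\lambda_1, \lambda_2) \ge 0}; otherwise it persists and the
#' minimal eigenvalue determines the dominant group (undetermined when
#' \eqn{|\lambda_1 - \lambda_2| < } `tie_tol`, since the theory requires
#' \eqn{\lambda_1 \ne \lambda_2}). The \eqn{\epsilon \to 0} closed forms
#' \eqn{-(a_{i,M} - c_i^2/4 - d)} are compared as a consistency check and a
#' warning is raised when the two orderings disagree.
#'
#' @param a1,a2 `bump_component`s (or single-bump lists) for the two groups.
#' @param c1,c2 shift speeds, \eqn{c_1 < 0 < c_2} expected.
#' @param d death rate.
#' @param epsilon mutation scale.
#' @param R ball radius per group (centered on each peak).
#' @param tie_tol dominance tie tolerance.
#' @return A `persistence_report`: `lambda` (length 2), `verdict`
#'   (`"extinct"`/`"persists"`), `dominant_index` (1, 2 or `NA` for
#'   undetermined), `lagged_fitness` (length 2, \eqn{a_{i,M} - c_i^2/4 - d}),
#'   `lambda_limit` (closed forms).
#' @export
persistence_classification <- function(a1, a2, c1, c2, d, epsilon, R = 20,
                                       tie_tol = 1e-6) {
  if (!(c1 < 0 && c2 > 0))
    warning("expected diverging speeds c1 < 0 < c2 (assumption B2)",
            call. = FALSE)
  bumps <- list(a1, a2); cs <- c(c1, c2)
  lam <- numeric(2); lagged <- numeric(2); lam0 <- numeric(2)
  for (i in 1:2) {
    b <- bumps[[i]]
    pot <- function(x) eval_bump(b, x) - cs[i]^2 / 4 - d
    pair <- principal_eigenpair_dirichlet(
      eigen_spec(pot, epsilon, R, center = b$center))
    lam[i] <- pair$lambda
    lagged[i] <- b$height - cs[i]^2 / 4 - d
    lam0[i] <- -lagged[i]
  }
  verdict <- if (min(lam) >= 0) "extinct" else "persists"
  dom <- if (abs(lam[1] - lam[2]) < tie_tol) NA_integer_
         else which.min(lam)
  dom0 <- if (abs(lam0[1] - lam0[2]) < tie_tol) NA_integer_
          else which.min(lam0)
  if (!is.na(dom) && !is.na(dom0) && dom != dom0)
    warning("finite-epsilon and limit orderings disagree: epsilon may be ",
            "too large for the asymptotic classification", call. = FALSE)
  structure(list(lambda = lam, verdict = verdict, dominant_index = dom,
                 lagged_fitness = lagged, lambda_limit = lam0,
                 epsilon = epsilon, speeds = cs),
            class = "persistence_report")
}

#' @exportS3Method base::print
print.persistence_report <- function(x, ...) {
  cat("<persistence_report>\n")
  cat(sprintf("  lambda = (%.6g, %.6g)  [limit (%.6g, %.6g)]\n",
              x$lambda[1], x$lambda[2], x$lambda_limit[1], x$lambda_limit[2]))
  cat(sprintf("  lagged fitness = (%.6g, %.6g)\n",
              x$lagged_fitness[1], x$lagged_fitness[2]))
  cat(sprintf("  verdict: %s; dominant group: %s\n", x$verdict,
              if (is.na(x$dominant_index)) "undetermined"
              else x$dominant_index))
  invisible(x)
}

#' Rayleigh quotient of a trial vector
#'
#' \eqn{\mathcal R[\phi] = (\epsilon^2 \sum |\Delta\phi/\Delta x|^2 -
#' \sum V \phi^2) / \sum \phi^2} on the Dirichlet ball; always at least the
#' principal eigenvalue.
#'
#' @param spec an `eigen_spec`.
#' @param phi trial vector over the interior nodes (extended by zero).
#' @return The Rayleigh quotient.
#' @export
rayleigh_quotient <- function(spec, phi) {
  nd <- spec_nodes(spec)
  stopifnot(length(phi) == length(nd$x))
  V <- spec$potential(nd$x)
  eps <- spec$epsilon
  ext <- c(0, phi, 0)
  grad2 <- sum(diff(ext)^2) / nd$dx^2
  (eps^2 * grad2 - sum(V * phi^2)) / sum(phi^2)
}
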