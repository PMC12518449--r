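# Fitness landscapes: compactly supported polynomial bumps minus a constant
# death rate, shifted linearly in time at trait-scaled speed eps * c.

#' Create a polynomial bump fitness component
#'
#' A bump evaluates to \eqn{(h - (x - x_0)^p)^+} in its own (frozen) frame:
#' nonnegative, continuous, compactly supported on
#' \eqn{|x - x_0| \le h^{1/p}}. Under a shift at speed `shift_speed` the
#' component is evaluated at \eqn{x - \epsilon c t}.
#'
#' @param center peak location \eqn{x_0} (trait units).
#' @param height peak height \eqn{h > 0} (per-time fitness).
#' @param exponent even integer \eqn{p \ge 2}.
#' @param shift_speed shift speed \eqn{c} (trait units per rescaled time).
#' @return An object of class `bump_component`.
#' @examples
#' b <- make_bump(35, 5/2, 4, 1)
#' eval_bump(b, 35)   # 2.5 at the center
#' @export
make_bump <- function(center, height, exponent, shift_speed = 0) {
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center))
  if (!is.numeric(height) || length(height) != 1L || height <= 0)
    stop("`height` must be a positive number", call. = FALSE)
  if (!is.numeric(exponent) || length(exponent) != 1L ||
      exponent != round(exponent) || exponent < 2 || exponent %% 2 != 0)
    stop("`exponent` must be an even integer >= 2", call. = FALSE)
  structure(
    list(center = center, height = height, exponent = as.integer(exponent),
         shift_speed = shift_speed,
         half_width = height^(1 / exponent)),
    class = "bump_component"
  )
}

#' Evaluate a bump component in its frozen frame
#'
#' @param bump a `bump_component`.
#' @param x numeric vector of trait values.
#' @return \eqn{(h - (x - x_0)^p)^+}, exactly zero outside the closed support.
#' @export
eval_bump <- function(bump, x) {
  pmax(bump$height - (x - bump$center)^bump$exponent, 0)
}

#' Compose a fitness landscape from bump components
#'
#' The landscape evaluates as
#' \eqn{a(x, t) = \sum_i b_i(x - \epsilon c_i t) - d}, continuous in
#' \eqn{(x, t)}. For `case_tag = "case1_common_speed"` all components must
#' share one shift speed; for `"case2_diverging"` there must be two speed
#' groups with \eqn{c_1 < 0 < c_2}.
#'
#' @param components list of `bump_component` objects (nonempty).
#' @param d constant death rate subtracted everywhere. Positive in the model's
#'   assumptions; any real value is accepted (the assumption checker warns
#'   when \eqn{d \le 0}).
#' @param case_tag `"case1_common_speed"` or `"case2_diverging"`.
#' @param epsilon mutation scale \eqn{\epsilon > 0} entering the shift
#'   \eqn{x - \epsilon c t}.
#' @return An object of class `fitness_landscape` with fields `components`,
#'   `d`, `case_tag`, `epsilon`, support interval (`support_lo`, `support_hi`),
#'   support radius `R0` (in the original coordinates) and `center`.
#' @export
compose_landscape <- function(components, d, case_tag = c("case1_common_speed",
                                                          "case2_diverging"),
                              epsilon = 0.1) {
  case_tag <- match.arg(case_tag)
  if (!is.list(components) || length(components) == 0L)
    stop("`components` must be a nonempty list of bump components",
         call. = FALSE)
  if (!all(vapply(components, inherits, logical(1), "bump_component")))
    stop("all components must be created by make_bump()", call. = FALSE)
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d),
            is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0)
  speeds <- vapply(components, `[[`, numeric(1), "shift_speed")
  if (case_tag == "case1_common_speed") {
    if (length(unique(speeds)) != 1L)
      stop("case1_common_speed requires all components to share one speed",
           call. = FALSE)
  } else {
    if (!(min(speeds) < 0 && max(speeds) > 0))
      stop("case2_diverging requires speeds c1 < 0 < c2 (assumption B2)",
           call. = FALSE)
  }
  lo <- min(vapply(components, function(b) b$center - b$half_width, numeric(1)))
  hi <- max(vapply(components, function(b) b$center + b$half_width, numeric(1)))
  structure(
    list(components = components, d = d, case_tag = case_tag,
         epsilon = epsilon, support_lo = lo, support_hi = hi,
         R0 = max(abs(c(lo, hi))), center = (lo + hi) / 2),
    class = "fitness_landscape"
  )
}

#' Build a landscape from an arbitrary callable
#'
#' For fitness shapes outside the polynomial-bump family:
#' \eqn{a(x, t) = f(x - \epsilon c t) - d} with `f` nonnegative and supported
#' (up to negligible tails) on `[support_lo, support_hi]`. Maxima and
#' curvatures of such landscapes come from grid refinement with
#' Richardson-extrapolated second differences rather than closed forms.
#'
#' @param fun vectorized function of the (frozen) trait.
#' @param d constant death rate.
#' @param support_lo,support_hi effective support of `fun`.
#' @param epsilon mutation scale.
#' @param shift_speed common shift speed `c`.
#' @return A `fitness_landscape` with an empty component list and a
#'   `custom_fun` field.
#' @export
custom_landscape <- function(fun, d, support_lo, support_hi, epsilon = 0.1,
                             shift_speed = 0) {
  stopifnot(is.function(fun), support_lo < support_hi, epsilon > 0)
  structure(
    list(components = list(), d = d, case_tag = "case1_common_speed",
         epsilon = epsilon, support_lo = support_lo,
         support_hi = support_hi,
         R0 = max(abs(c(support_lo, support_hi))),
         center = (support_lo + support_hi) / 2,
         custom_fun = fun, shift_speed = shift_speed),
    class = "fitness_landscape"
  )
}

#' Evaluate a fitness landscape
#'
#' @param landscape a `fitness_landscape`.
#' @param x numeric vector of trait values.
#' @param t time (default 0, the frozen frame).
#' @return \eqn{a(x, t)} as a numeric vector.
#' @export
eval_landscape <- function(landscape, x, t = 0) {
  a <- rep(-landscape$d, length(x))
  if (!is.null(landscape$custom_fun))
    return(a + landscape$custom_fun(
      x - landscape$epsilon * landscape$shift_speed * t))
  for (b in landscape$components)
    a <- a + eval_bump(b, x - landscape$epsilon * b$shift_speed * t)
  a
}

#' @exportS3Method base::print
print.fitness_landscape <- function(x, ...) {
  cat("<fitness_landscape> (", x$case_tag, ")\n", sep = "")
  for (b in x$components)
    cat(sprintf("  bump: center %g, height %g, exponent %d, speed %g\n",
                b$center, b$height, b$exponent, b$shift_speed))
  cat(sprintf("  d = %g, epsilon = %g, support [%g, %g]\n",
              x$d, x$epsilon, x$support_lo, x$support_hi))
  invisible(x)
}

# Frozen-frame landscape for component group moving at speed `c` (case 2:
# one bump per group); case 1: the whole landscape at t = 0.
frozen_values <- function(landscape, x) eval_landscape(landscape, x, t = 0)

#' Locate the global maxima of the frozen-frame landscape
#'
#' Candidate maxima are the component centers (the exact maxima of isolated
#' bumps), refined on a fine probe grid to catch maxima created by overlapping
#' supports. The curvature magnitude \eqn{|a''|} at each maximum is the exact
#' second derivative of the active polynomial pieces (zero for exponents
#' greater than 2 at their own center).
#'
#' @param landscape a `fitness_landscape`.
#' @param tol values within `tol` of the maximum count as global maxima.
#' @return A data frame with columns `location`, `value`,
#'   `curvature_magnitude`, ordered by location.
#' @export
global_maxima <- function(landscape, tol = 1e-9) {
  if (!is.null(landscape$custom_fun))
    return(global_maxima_grid(landscape, tol))
  centers <- vapply(landscape$components, `[[`, numeric(1), "center")
  lo <- landscape$support_lo; hi <- landscape$support_hi
  probe <- seq(lo - 1, hi + 1, by = 1e-3)
  av <- frozen_values(landscape, probe)
  a_M <- max(max(av), max(frozen_values(landscape, centers)))
  # candidates: centers (exact maxima of isolated bumps) plus probe-grid
  # local maxima away from all centers (maxima created by overlap), polished
  # by golden-section refinement and snapped back to a center when within
  # the refinement noise of one
  cand <- centers
  idx <- which(av > a_M - 10 * tol)
  if (length(idx)) {
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    extra <- vapply(runs, function(r) probe[r[which.max(av[r])]], numeric(1))
    extra <- extra[vapply(extra, function(e) min(abs(e - centers)) > 0.05,
                          logical(1))]
    extra <- vapply(extra, function(x0) {
      stats::optimize(function(x) -frozen_values(landscape, x),
                      lower = x0 - 2e-3, upper = x0 + 2e-3,
                      tol = 1e-12)$minimum
    }, numeric(1))
    cand <- c(cand, extra)
  }
  vals <- frozen_values(landscape, cand)
  keep <- vals >= a_M - tol
  cand <- cand[keep]; vals <- vals[keep]
  ord <- order(cand)
  cand <- cand[ord]; vals <- vals[ord]
  if (length(cand) > 1) {
    dup <- c(FALSE, diff(cand) < 1e-3)
    cand <- cand[!dup]; vals <- vals[!dup]
  }
  # a genuine continuum of maxima is flat over an O(1) trait range; a high-
  # exponent bump is only flat over ~tol^(1/p)
  plateau <- mean(av > a_M - tol) * (length(probe) * 1e-3)
  if (plateau > 0.2)
    stop("non-isolated global maxima (flat top); assumption (A4) fails",
         call. = FALSE)
  curv <- vapply(cand, function(x0) landscape_curvature(landscape, x0),
                 numeric(1))
  data.frame(location = cand, value = vals, curvature_magnitude = abs(curv))
}

# grid-refinement maxima for callable landscapes: probe grid, golden-section
# polish, Richardson-extrapolated central second differences (step 1e-3)
global_maxima_grid <- function(landscape, tol = 1e-9) {
  lo <- landscape$support_lo; hi <- landscape$support_hi
  probe <- seq(lo - 1, hi + 1, by = 1e-3)
  av <- frozen_values(landscape, probe)
  a_M <- max(av)
  idx <- which(av > a_M - 1e-6)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  if (mean(av > a_M - tol) * (length(probe) * 1e-3) > 0.2)
    stop("non-isolated global maxima (flat top); assumption (A4) fails",
         call. = FALSE)
  cand <- vapply(runs, function(r) {
    x0 <- probe[r[which.max(av[r])]]
    stats::optimize(function(x) -frozen_values(landscape, x),
                    lower = x0 - 2e-3, upper = x0 + 2e-3, tol = 1e-12)$minimum
  }, numeric(1))
  cand <- sort(cand)
  vals <- frozen_values(landscape, cand)
  keep <- vals >= max(vals) - tol
  cand <- cand[keep]; vals <- vals[keep]
  d2 <- vapply(cand, function(x0) {
    h <- 1e-3
    f <- function(s) frozen_values(landscape, s)
    d2h <- (f(x0 + h) - 2 * f(x0) + f(x0 - h)) / h^2
    d2h2 <- (f(x0 + h / 2) - 2 * f(x0) + f(x0 - h / 2)) / (h / 2)^2
    (4 * d2h2 - d2h) / 3   # one Richardson refinement
  }, numeric(1))
  data.frame(location = cand, value = vals, curvature_magnitude = abs(d2))
}

# exact second derivative of the polynomial pieces active at interior point x0
landscape_curvature <- function(landscape, x0) {
  if (!is.null(landscape$custom_fun)) {
    h <- 1e-3
    f <- function(s) frozen_values(landscape, s)
    d2h <- (f(x0 + h) - 2 * f(x0) + f(x0 - h)) / h^2
    d2h2 <- (f(x0 + h / 2) - 2 * f(x0) + f(x0 - h / 2)) / (h / 2)^2
    return((4 * d2h2 - d2h) / 3)
  }
  d2 <- 0
  for (b in landscape$components) {
    if (abs(x0 - b$center) < b$half_width - 1e-12) {
      p <- b$exponent
      d2 <- d2 - p * (p - 1) * (x0 - b$center)^(p - 2)
    }
  }
  d2
}

# first derivative (one-sided pieces ignored at support kinks)
landscape_slope <- function(landscape, x0) {
  d1 <- 0
  for (b in landscape$components) {
    if (abs(x0 - b$center) < b$half_width - 1e-12) {
      p <- b$exponent
      d1 <- d1 - p * (x0 - b$center)^(p - 1)
    }
  }
  d1
}

#' Lagged optima of a shifting landscape
#'
#' For a landscape shifting at speed `c`, the population can at best realise
#' the lagged fitness \eqn{a_M - c^2/4}. The lagged optimum attached to a peak
#' \eqn{x_i} is the solution of \eqn{a(\bar x) = a_M - c^2/4} on the side of
#' the peak where \eqn{a'(\bar x) > 0} for \eqn{c > 0} (the trait strictly
#' behind the moving peak; mirrored for \eqn{c < 0}; the peak itself for
#' \eqn{c = 0}).
#'
#' @param landscape a `fitness_landscape` (frozen frame).
#' @param c shift speed used for the lag level.
#' @return A data frame with columns `peak`, `x_bar`, `lagged_fitness`,
#'   `slope` (sign-checked finite difference of \eqn{a} at `x_bar`). Empty
#'   when the lag level falls below the off-support fitness level.
#' @export
lagged_optima <- function(landscape, c) {
  peaks <- global_maxima(landscape)
  a_M <- max(peaks$value)
  level <- a_M - c^2 / 4
  if (level <= -landscape$d + 1e-12)
    return(data.frame(peak = numeric(0), x_bar = numeric(0),
                      lagged_fitness = numeric(0), slope = numeric(0)))
  f <- function(x) frozen_values(landscape, x) - level
  out <- lapply(seq_len(nrow(peaks)), function(i) {
    xi <- peaks$location[i]
    if (c == 0) {
      return(data.frame(peak = xi, x_bar = xi, lagged_fitness = level,
                        slope = 0))
    }
    dir <- if (c > 0) -1 else 1   # search behind the shift direction
    # bracket: step away from the peak until a < level
    step <- 1e-3; xout <- xi
    repeat {
      xout <- xi + dir * step
      if (f(xout) < 0) break
      step <- step * 1.5
      if (step > (landscape$support_hi - landscape$support_lo) + 10)
        stop("bracketing failed for the lag level; check assumption (A5)",
             call. = FALSE)
    }
    r <- stats::uniroot(f, lower = min(xi, xout), upper = max(xi, xout),
                        tol = 1e-12)
    xb <- r$root
    h <- 1e-6
    sl <- (frozen_values(landscape, xb + h) -
             frozen_values(landscape, xb - h)) / (2 * h)
    data.frame(peak = xi, x_bar = xb, lagged_fitness = level, slope = sl)
  })
  do.call(rbind, out)
}

#' Check the structural assumptions on a landscape
#'
#' Probes, on a dense grid: negativity beyond the support (A1), boundedness
#' (A2), finitely many ordered maxima (A4/B4), and the exact level-crossing
#' counts of \eqn{a(x) = a_M - c^2/4} required by (A5)/(B5): two crossings in
#' each interval between consecutive peaks and one in the outer interval on
#' the lagged side.
#'
#' @param landscape a `fitness_landscape`.
#' @param c shift speed (Case 1) or a length-2 vector `c(c1, c2)` (Case 2,
#'   checked per component group).
#' @return A data frame of class `assumption_report` with columns
#'   `assumption`, `pass`, `detail`. A warning (not a failure) is attached
#'   when \eqn{d \le 0}.
#' @export
validate_assumptions <- function(landscape, c) {
  rows <- list()
  add <- function(name, pass, detail)
    rows[[length(rows) + 1L]] <<- data.frame(assumption = name, pass = pass,
                                             detail = detail)
  if (landscape$d <= 0)
    warning("death rate d <= 0: the model assumes d > 0 (caption values ",
            "d = -1/2 are accepted but flagged)", call. = FALSE)
  lo <- landscape$support_lo; hi <- landscape$support_hi
  probe <- seq(lo - 5, hi + 5, by = 1e-3)
  av <- frozen_values(landscape, probe)
  outside <- probe < lo | probe > hi
  dprime <- if (landscape$d > 0) landscape$d / 2 else -Inf
  add("A1_negative_tail", all(av[outside] < -dprime),
      sprintf("a = %g beyond the support", -landscape$d))
  add("A2_bounded", all(is.finite(av)),
      sprintf("range [%g, %g]", min(av), max(av)))
  peaks <- tryCatch(global_maxima(landscape), error = function(e) NULL)
  if (is.null(peaks)) {
    add("A4_finite_maxima", FALSE, "non-isolated maxima detected")
    out <- do.call(rbind, rows)
    class(out) <- c("assumption_report", class(out))
    return(out)
  }
  add("A4_finite_maxima", nrow(peaks) >= 1 &&
        all(diff(peaks$location) > 0),
      sprintf("%d maxima at %s", nrow(peaks),
              paste(signif(peaks$location, 6), collapse = ", ")))
  if (landscape$case_tag == "case1_common_speed") {
    stopifnot(length(c) == 1L)
    rows_a5 <- check_crossings(landscape, peaks, c)
    add("A5_crossing_counts", rows_a5$pass, rows_a5$detail)
  } else {
    stopifnot(length(c) == 2L)
    speeds <- vapply(landscape$components, `[[`, numeric(1), "shift_speed")
    for (k in 1:2) {
      comp_k <- landscape$components[sign(speeds) == sign(c[k])]
      sub <- compose_landscape(comp_k, d = landscape$d,
                               case_tag = "case1_common_speed",
                               epsilon = landscape$epsilon)
      pk <- global_maxima(sub)
      rk <- check_crossings(sub, pk, c[k])
      add(paste0("B5_crossing_counts_a", k), rk$pass, rk$detail)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("assumption_report", class(out))
  out
}

# count solutions of a(x) = a_M - c^2/4 between and outside peaks
check_crossings <- function(landscape, peaks, c) {
  a_M <- max(peaks$value)
  level <- a_M - c^2 / 4
  lo <- landscape$support_lo; hi <- landscape$support_hi
  probe <- seq(lo - 2, hi + 2, by = 1e-4)
  f <- frozen_values(landscape, probe) - level
  crossings <- probe[which(diff(sign(f)) != 0)]
  locs <- function(a, b) crossings[crossings > a & crossings < b]
  ok <- TRUE; msgs <- character(0)
  n <- nrow(peaks)
  if (n >= 2) {
    for (i in 2:n) {
      k <- length(locs(peaks$location[i - 1], peaks$location[i]))
      if (k != 2) ok <- FALSE
      msgs <- c(msgs, sprintf("(%g,%g): %d", peaks$location[i - 1],
                              peaks$location[i], k))
    }
  }
  outer_n <- if (c >= 0) length(locs(-Inf, peaks$location[1]))
             else length(locs(peaks$location[n], Inf))
  if (outer_n != 1) ok <- FALSE
  msgs <- c(msgs, sprintf("outer: %d", outer_n))
  if (level <= -landscape$d) {
    ok <- FALSE
    msgs <- c(msgs, sprintf("lag level %g below off-support fitness %g",
                            level, -landscape$d))
  }
  list(pass = ok, detail = paste(msgs, collapse = "; "))
}

#' Gaussian initial density
#'
#' The default initial condition \eqn{n_0(x) = A e^{-(x - \mu)^2 / s^2}} with
#' the decay-envelope constants \eqn{(C_1, C_2)} of assumption (A3) attached.
#'
#' @param mean,width,amplitude Gaussian parameters (defaults: the preset
#'   initial condition \eqn{\frac{1}{10} e^{-(x-37.5)^2/10^2}}).
#' @param C1,C2 envelope constants; `validate_initial_condition` checks
#'   \eqn{0 \le n_0 \le e^{C_1 - C_2 |x|}} on a grid.
#' @return A function of `x` with attributes `C1`, `C2`.
#' @export
init_gaussian <- function(mean = 37.5, width = 10, amplitude = 1 / 10,
                          C1 = 0, C2 = 0.05) {
  f <- function(x) amplitude * exp(-(x - mean)^2 / width^2)
  attr(f, "C1") <- C1
  attr(f, "C2") <- C2
  f
}

#' @rdname init_gaussian
#' @param n0 initial-density function.
#' @param x grid on which to check the envelope.
#' @export
validate_initial_condition <- function(n0, x) {
  C1 <- attr(n0, "C1") %||% 0
  C2 <- attr(n0, "C2") %||% 0.05
  v <- n0(x)
  all(v >= 0) && all(v <= exp(C1 - C2 * abs(x)) + 1e-12)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Named landscape presets
#'
#' Parameter sets printed in the numerical-experiment captions. Available
#' presets: `"fig4"`/`"fig5"` (quartic peak at 35 and quadratic peak at 40,
#' equal heights 5/2, common speed 1, d = 1/2, eps = 0.1), `"fig6"` (heights
#' 7/4 at 32 and 5/2 at 48, speeds −1 and `c2`, d = −1/2, eps = 0.1),
#' `"fig7"` (as fig6 with peaks at 28+z and 52−z), `"fig8"` (both peaks at
#' 40, heights 7/4 and 5/2, speeds ∓6/5, d = 1/2, eps = 0.05), and
#' `"peak1"` (single quadratic peak at 40, height 5/2, speed 1, d = 1/2;
#' the single-peak workhorse).
#'
#' @param name preset name.
#' @param c2 Case-2 right-moving speed override (fig6/fig7).
#' @param z fig7 peak-separation parameter (caption values 12, 8, 4, 0).
#' @param epsilon optional mutation-scale override.
#' @return A `fitness_landscape` with attribute `n0` (initial density
#'   function) and attribute `c` (speed scalar for Case 1, pair for Case 2).
#' @export
preset_landscape <- function(name, c2 = 2.5, z = 4, epsilon = NULL) {
  presets <- c("fig4", "fig5", "fig6", "fig7", "fig8", "peak1")
  if (!name %in% presets)
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "), call. = FALSE)
  eps <- epsilon
  ls <- switch(name,
    fig4 = ,
    fig5 = {
      eps <- eps %||% 0.1
      compose_landscape(list(make_bump(35, 5/2, 4, 1),
                             make_bump(40, 5/2, 2, 1)),
                        d = 1/2, case_tag = "case1_common_speed",
                        epsilon = eps)
    },
    fig6 = {
      eps <- eps %||% 0.1
      compose_landscape(list(make_bump(32, 7/4, 2, -1),
                             make_bump(48, 5/2, 2, c2)),
                        d = -1/2, case_tag = "case2_diverging",
                        epsilon = eps)
    },
    fig7 = {
      eps <- eps %||% 0.1
      compose_landscape(list(make_bump(28 + z, 7/4, 2, -1),
                             make_bump(52 - z, 5/2, 2, c2)),
                        d = -1/2, case_tag = "case2_diverging",
                        epsilon = eps)
    },
    fig8 = {
      eps <- eps %||% 0.05
      compose_landscape(list(make_bump(40, 7/4, 2, -6/5),
                             make_bump(40, 5/2, 2, 6/5)),
                        d = 1/2, case_tag = "case2_diverging",
                        epsilon = eps)
    },
    peak1 = {
      eps <- eps %||% 0.1
      compose_landscape(list(make_bump(40, 5/2, 2, 1)),
                        d = 1/2, case_tag = "case1_common_speed",
                        epsilon = eps)
    }
  )
  attr(ls, "n0") <- init_gaussian()
  attr(ls, "c") <- if (ls$case_tag == "case1_common_speed")
    ls$components[[1]]$shift_speed
  else vapply(ls$components, `[[`, numeric(1), "shift_speed")
  attr(ls, "preset") <- name
  ls
}
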