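# Experiment presets, configuration, report assembly and a small CLI.
# Presets reproduce the published experiments at reduced scale; every run is
# fully deterministic (there is no randomness anywhere in the pipeline).

#' Build an experiment configuration
#'
#' @param preset preset name (see [preset_landscape()]) or `NULL` with an
#'   explicit `landscape`.
#' @param landscape explicit `fitness_landscape` (overrides `preset`).
#' @param scheme `"fd"`, `"hj_eps"` or `"hj_limit"`.
#' @param L,Nx trait-grid parameters.
#' @param T horizon: PDE time for `"fd"`, rescaled time for the HJ schemes.
#'   Default per preset (scaled-down runs).
#' @param epsilon mutation-scale override.
#' @param c2,z preset overrides (see [preset_landscape()]).
#' @param snapshot_stride snapshot stride for `"fd"`.
#' @param out optional output directory for plain-text tables.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(preset = NULL, landscape = NULL,
                              scheme = c("fd", "hj_eps", "hj_limit"),
                              L = 80, Nx = 1600, T = NULL, epsilon = NULL,
                              c2 = 2.5, z = 4, snapshot_stride = 100,
                              out = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(landscape)) {
    if (is.null(preset)) stop("supply a preset or a landscape", call. = FALSE)
    landscape <- preset_landscape(preset, c2 = c2, z = z, epsilon = epsilon)
  }
  if (is.null(T)) {
    T <- switch(attr(landscape, "preset") %||% "custom",
                fig4 = 80, fig5 = 2, fig6 = 40, fig7 = 40, fig8 = 40,
                peak1 = 60, 50)
    if (scheme != "fd") T <- min(T, 2)
  }
  structure(list(preset = preset, landscape = landscape, scheme = scheme,
                 L = L, Nx = Nx, T = T,
                 epsilon = epsilon %||% landscape$epsilon,
                 snapshot_stride = snapshot_stride, out = out),
            class = "experiment_config")
}

# default phase initial condition (fig5 caption):
# u0 = -eps (log(1/10) - (x - 37.5)^2 / 10^2)
phase_ic <- function(epsilon) {
  function(x) -epsilon * (log(1 / 10) - (x - 37.5)^2 / 10^2)
}

#' Run an experiment
#'
#' Runs the configured scheme on the configured landscape, assembles the
#' theory-versus-simulation summary (dominant candidate, eigenvalue, limiting
#' mass, overtaking flag for the two-speed case) and optionally writes
#' plain-text tables.
#'
#' @param config an `experiment_config`.
#' @return An `experiment_result`: `config`, `trajectory`, `summary` (list).
#' @export
run_experiment <- function(config) {
  ls <- config$landscape
  grid <- trait_grid(config$L, config$Nx)
  n0 <- attr(ls, "n0") %||% init_gaussian()
  cc <- attr(ls, "c")
  if (config$scheme %in% c("hj_eps", "hj_limit")) {
    if (ls$case_tag != "case1_common_speed")
      stop("HJ schemes require a common shift speed (Case 1)", call. = FALSE)
    eps <- if (config$scheme == "hj_eps") config$epsilon else NULL
    traj <- hj_run(ls, phase_ic(config$epsilon), grid, T = config$T,
                   c = cc, epsilon = eps)
    pred <- concentration_points(ls, cc)
    target <- pred$x_bar[pred$shallowest][1]
    summary <- list(scheme = config$scheme,
                    final_argmin = traj$argmin[length(traj$argmin)],
                    predicted_x_bar = target,
                    argmin_error = abs(traj$argmin[length(traj$argmin)] -
                                         target),
                    final_mass = traj$mass[length(traj$mass)])
  } else if (ls$case_tag == "case1_common_speed") {
    traj <- fd_run(ls, n0, grid, T = config$T,
                   snapshot_stride = config$snapshot_stride)
    pred <- concentration_points(ls, cc)
    final <- traj$snapshots[[length(traj$snapshots)]]
    rep <- if (nrow(pred)) {
      com <- comoving(final, cc, config$epsilon)
      locate_mass(com, pred$x_bar, epsilon = config$epsilon)
    } else NULL
    pair <- principal_eigenpair_drift(ls, cc, config$epsilon, R = 30)
    rl <- rho_limit_check(traj$times, traj$rho, pair$lambda)
    summary <- list(scheme = "fd", prediction = pred,
                    concentration = rep,
                    dominant_candidate =
                      if (!is.null(rep) && !is.na(rep$dominant))
                        pred$x_bar[rep$dominant] else NA_real_,
                    lambda = pair$lambda, rho_check = rl,
                    verdict = if (rl$extinct) "extinct" else "persists")
  } else {
    traj <- fd_run(ls, n0, grid, T = config$T,
                   snapshot_stride = config$snapshot_stride)
    speeds <- vapply(ls$components, `[[`, numeric(1), "shift_speed")
    i1 <- which(speeds < 0)[1]; i2 <- which(speeds > 0)[1]
    b1 <- ls$components[[i1]]; b2 <- ls$components[[i2]]
    cls <- persistence_classification(b1, b2, speeds[i1], speeds[i2],
                                      d = ls$d, epsilon = config$epsilon)
    xb1 <- b1$center + abs(speeds[i1]) / 2   # behind a left-moving peak
    xb2 <- b2$center - speeds[i2] / 2        # behind a right-moving peak
    eps <- config$epsilon
    tracks <- list(function(t) xb1 + eps * speeds[i1] * t,
                   function(t) xb2 + eps * speeds[i2] * t)
    tf <- track_fractions(traj, tracks, w = 2.5)
    nfin <- nrow(tf)
    early <- tf[tf$time <= config$T / 2, ]
    overtaking <- any(early$frac_2 > early$frac_1, na.rm = TRUE) &&
      tf$frac_1[nfin] > tf$frac_2[nfin]
    rl <- rho_limit_check(traj$times, traj$rho, min(cls$lambda))
    summary <- list(scheme = "fd", classification = cls,
                    track_fractions = tf,
                    dominant_track = if (tf$frac_1[nfin] > tf$frac_2[nfin])
                      1L else 2L,
                    transient_overtaking = overtaking,
                    rho_check = rl, verdict = cls$verdict,
                    rho_eventually_monotone = isTRUE(rl$tail_monotone))
  }
  res <- structure(list(config = config, trajectory = traj,
                        summary = summary),
                   class = "experiment_result")
  if (!is.null(config$out)) write_experiment(res, config$out)
  res
}

write_experiment <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  traj <- res$trajectory
  if (inherits(traj, "fd_trajectory")) {
    write_mass_series(traj, file.path(dir, "mass_series.csv"))
    snap <- traj$snapshots[[length(traj$snapshots)]]
    utils::write.csv(data.frame(x = snap$grid$x, density = snap$density),
                     file.path(dir, "final_density.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(data.frame(time = traj$times, mass = traj$mass,
                                argmin = traj$argmin),
                     file.path(dir, "phase_series.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  s <- res$summary
  keep <- vapply(s, function(v) is.atomic(v) && length(v) == 1, logical(1))
  writeLines(paste(names(s)[keep],
                   vapply(s[keep], function(v) format(v, digits = 10),
                          character(1)), sep = ","),
             file.path(dir, "summary.csv"))
  invisible(dir)
}

#' Sweep one parameter over a set of values
#'
#' Re-runs the (cheap) spectral classification — and optionally the full
#' simulation — for each value of `c2`, `epsilon` or `d` and brackets the
#' value at which the dominant group flips.
#'
#' @param config a Case-2 `experiment_config` (fig6/fig7 style), or
#'   Case 1 for `parameter = "epsilon"`.
#' @param parameter `"c2"`, `"epsilon"` or `"d"`.
#' @param values parameter values (finite).
#' @param simulate also run the full simulation per value (slow).
#' @return A `sweep_result`: `table` (one row per value: eigenvalues,
#'   dominant index), `switch_bracket` (length-2 or `NULL`).
#' @export
sweep_parameter <- function(config, parameter = c("c2", "epsilon", "d"),
                            values, simulate = FALSE) {
  parameter <- match.arg(parameter)
  if (length(values) == 0)
    return(structure(list(table = data.frame(), switch_bracket = NULL),
                     class = "sweep_result"))
  stopifnot(all(is.finite(values)))
  rows <- lapply(values, function(v) {
    ls <- config$landscape
    if (parameter == "c2") {
      ls <- preset_landscape(attr(ls, "preset") %||% "fig6", c2 = v,
                             epsilon = config$epsilon)
    }
    speeds <- vapply(ls$components, `[[`, numeric(1), "shift_speed")
    i1 <- which(speeds < 0)[1]; i2 <- which(speeds > 0)[1]
    d_use <- if (parameter == "d") v else ls$d
    eps_use <- if (parameter == "epsilon") v else config$epsilon
    cls <- persistence_classification(ls$components[[i1]],
                                      ls$components[[i2]],
                                      speeds[i1], speeds[i2],
                                      d = d_use, epsilon = eps_use)
    data.frame(value = v, lambda1 = cls$lambda[1], lambda2 = cls$lambda[2],
               dominant = cls$dominant_index, verdict = cls$verdict,
               lagged1 = cls$lagged_fitness[1],
               lagged2 = cls$lagged_fitness[2])
  })
  tab <- do.call(rbind, rows)
  bracket <- NULL
  det <- which(!is.na(tab$dominant))
  if (length(det) >= 2 && length(unique(tab$dominant[det])) == 2) {
    first_dom <- tab$dominant[det[1]]
    first_new <- min(det[tab$dominant[det] != first_dom])
    # a tie row at the crossover itself belongs to the lower endpoint
    bracket <- c(tab$value[first_new - 1L], tab$value[first_new])
  }
  structure(list(table = tab, switch_bracket = bracket,
                 parameter = parameter),
            class = "sweep_result")
}

#' Read / write a flat key-value configuration file
#'
#' A YAML-compatible subset: one `key: value` pair per line, `#` comments.
#'
#' @param path file path.
#' @return A named list (strings coerced to numbers where possible).
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  out <- list()
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar values.
#' @export
write_config <- function(config, path) {
  writeLines(paste0(names(config), ": ",
                    vapply(config, function(v) format(v, digits = 12),
                           character(1))), path)
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `eigen`, `lagged`, `hj`, `sweep`, `report`.
#' Common flags: `--preset`, `--config`, `--epsilon`, `--c`, `--c1`, `--c2`,
#' `--scheme`, `--out`, `--T`.
#'
#' @param args character vector of CLI arguments (default: the command line).
#' @return Invisibly, the computed object; called for its side effects.
#' @export
shiftpeaks_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: shiftpeaks <simulate|eigen|lagged|hj|sweep|report> ",
         "[--preset name] [--epsilon e] [--c c] [--c2 c2] [--scheme s] ",
         "[--T T] [--out dir]", call. = FALSE)
  cmd <- args[1]
  spec <- list(
    optparse::make_option("--preset", type = "character", default = "fig4"),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--epsilon", type = "double", default = NULL),
    optparse::make_option("--c", type = "double", default = NULL),
    optparse::make_option("--c1", type = "double", default = -1),
    optparse::make_option("--c2", type = "double", default = 2.5),
    optparse::make_option("--scheme", type = "character", default = "fd"),
    optparse::make_option("--T", type = "double", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--values", type = "character",
                          default = "1,1.5,2,2.5")
  )
  opt <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                              args = args[-1])
  if (!is.null(opt$config)) {
    cfg_file <- read_config(opt$config)
    for (k in names(cfg_file)) opt[[k]] <- cfg_file[[k]]
  }
  cfg <- experiment_config(preset = opt$preset, scheme = opt$scheme,
                           T = opt$T, epsilon = opt$epsilon, c2 = opt$c2,
                           out = opt$out)
  ls <- cfg$landscape
  cc <- opt$c %||% attr(ls, "c")[1]
  out <- switch(cmd,
    simulate = ,
    report = run_experiment(cfg),
    hj = {
      cfg$scheme <- if (opt$scheme %in% c("hj_eps", "hj_limit"))
        opt$scheme else "hj_eps"
      run_experiment(cfg)
    },
    eigen = principal_eigenpair_drift(ls, cc, cfg$epsilon, R = 30),
    lagged = lagged_optima(ls, cc),
    sweep = {
      vals <- as.numeric(strsplit(opt$values, ",")[[1]])
      sweep_parameter(cfg, "c2", vals)
    },
    stop("unknown subcommand '", cmd, "'; available: simulate, eigen, ",
         "lagged, hj, sweep, report", call. = FALSE)
  )
  if (cmd %in% c("eigen")) {
    cat(sprintf("lambda = %.8g (epsilon %g, R %g)\n", out$lambda,
                out$epsilon, out$R))
  } else if (cmd == "lagged") {
    print(out)
  } else if (cmd == "sweep") {
    print(out$table)
    if (!is.null(out$switch_bracket))
      cat(sprintf("dominant index switches in (%g, %g]\n",
                  out$switch_bracket[1], out$switch_bracket[2]))
  }
  invisible(out)
}
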