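#' Experiment scenario
#'
#' A fully specified, deterministic simulation configuration: initial
#' fixture, potential, discretization, shape, weighting, velocity strategy
#' and method. The defaults mirror the validation setting (quadratic
#' potential, cubic B-spline shapes, cell-integral weights, grid-quadrature
#' velocities). For singular potentials (`1 < a < 2` or `1 < b < 2`) a time
#' step much larger than `100 * h^2` triggers a warning: the singular
#' convergence regime requires a parabolic-type step restriction.
#'
#' @param fixture fixture name (see [fixture_density()]) or a density
#'   function with a `support` attribute.
#' @param potential potential specification (see [parse_potential()]).
#' @param h initial particle spacing.
#' @param dt time step.
#' @param t_end final time.
#' @param shape shape name (`"hat"`, `"b3"`) or [ltp_shape()].
#' @param weights `"cell_integral"` or `"dual_kernel"`.
#' @param velocity velocity strategy name or [velocity_evaluator()].
#' @param method `"ltp"` or `"sp"` (fixed-width reconstruction of the same
#'   run; see [sp_density()]).
#' @param sp_eps SP reconstruction width (default `h`).
#' @param normalize normalize the fixture to unit mass (default `TRUE`).
#' @param snapshot_times times at which to store/write snapshots.
#' @param blowup_ceiling concentration-guard ceiling for `max(1/hvol)`.
#' @param jacobian_mode `"exponential"` or `"linearized"`.
#' @param grid_margin extra margin (in units of the fixture support) for
#'   the initialization bounds.
#' @return An object of class `ltp_scenario`.
#' @export
scenario <- function(fixture = "rho1", potential = "quadratic",
                     h = 1 / 25, dt = 1e-3, t_end = 0.5,
                     shape = "b3", weights = c("cell_integral", "dual_kernel"),
                     velocity = "quadrature", method = c("ltp", "sp"),
                     sp_eps = NULL, normalize = TRUE,
                     snapshot_times = numeric(), blowup_ceiling = 1e8,
                     jacobian_mode = c("exponential", "linearized"),
                     grid_margin = 0) {
  weights <- match.arg(weights)
  method <- match.arg(method)
  jacobian_mode <- match.arg(jacobian_mode)
  stopifnot(h > 0, dt > 0, t_end > 0)
  if (is.character(fixture)) fixture <- fixture_density(fixture)
  if (is.character(shape)) shape <- ltp_shape(shape)
  pot <- parse_potential(potential)
  if (!pot$is_smooth && dt > 100 * h^2) {
    warning(sprintf(
      "singular potential with dt = %g > 100 h^2 = %g; expect reduced accuracy",
      dt, 100 * h^2))
  }
  if (is.character(velocity)) velocity <- velocity_evaluator(velocity)
  structure(
    list(fixture = fixture, potential = pot, h = h, dt = dt, t_end = t_end,
         shape = shape, weights = weights, velocity = velocity,
         method = method, sp_eps = sp_eps %||% h, normalize = normalize,
         snapshot_times = snapshot_times, blowup_ceiling = blowup_ceiling,
         jacobian_mode = jacobian_mode, grid_margin = grid_margin),
    class = "ltp_scenario"
  )
}

#' @export
print.ltp_scenario <- function(x, ...) {
  cat(sprintf(
    "<ltp_scenario>  fixture '%s', potential '%s', h = %g, dt = %g, T = %g\n",
    attr(x$fixture, "name") %||% "custom", x$potential$name, x$h, x$dt, x$t_end))
  cat(sprintf("  shape '%s', weights '%s', velocity '%s', method '%s'\n",
              x$shape$name, x$weights, x$velocity$strategy, x$method))
  invisible(x)
}

scenario_initial_ensemble <- function(sc) {
  support <- attr(sc$fixture, "support") %||% c(-1, 1)
  margin <- sc$grid_margin * diff(support)
  grid <- init_grid(sc$h, c(support[1] - margin, support[2] + margin))
  build_initial_ensemble(sc$fixture, grid, shape = sc$shape,
                         scheme = sc$weights, normalize = sc$normalize)
}

scenario_rho0 <- function(sc) {
  if (sc$normalize && !isTRUE(attr(sc$fixture, "normalized"))) {
    normalize_density(sc$fixture)
  } else {
    sc$fixture
  }
}

#' Run a scenario end to end
#'
#' Builds the initial ensemble, runs the LTP scheme, and (for the quadratic
#' potential) computes error reports against the closed-form solution at
#' every snapshot time. When `outdir` is given, writes plain-text artifacts:
#' per-snapshot particle tables (`particles_<t>.csv`: columns `k`, `x`,
#' `omega`, `D`, `h_vol`), gridded density tables (`density_<t>.csv`:
#' `x`, `rho`, plus `rho_sp` for the SP baseline), the per-step run log
#' (`runlog.csv`), an error table (`errors.csv`, quadratic only) and a JSON
#' manifest of all parameters (`manifest.json`). Runs are deterministic:
#' repeated invocations produce identical results.
#'
#' @param sc an [scenario()].
#' @param outdir optional output directory (created if missing).
#' @param density_grid optional evaluation grid for density tables and
#'   errors; default spacing `h/8` over the initial support plus margin.
#' @return A list with `run` (the [ltp_run()] result), `ensemble0`,
#'   `errors` (quadratic only), `density_grid`, `scenario`.
#' @export
run_scenario <- function(sc, outdir = NULL, density_grid = NULL) {
  stopifnot(inherits(sc, "ltp_scenario"))
  ens0 <- scenario_initial_ensemble(sc)
  rho0 <- scenario_rho0(sc)
  run <- ltp_run(ens0, sc$potential, sc$velocity, dt = sc$dt,
                 t_end = sc$t_end, snapshot_times = sc$snapshot_times,
                 blowup_ceiling = sc$blowup_ceiling,
                 jacobian_mode = sc$jacobian_mode)
  support <- attr(rho0, "support") %||% c(-1, 1)
  if (is.null(density_grid)) {
    margin <- sc$shape$support_radius * sc$h + 0.1 * diff(support)
    density_grid <- seq(support[1] - margin, support[2] + margin, by = sc$h / 8)
  }
  errors <- NULL
  if (sc$potential$name == "quadratic") {
    lambda <- center_of_mass(rho0)
    times <- as.numeric(names(run$snapshots))
    errors <- do.call(rbind, lapply(seq_along(run$snapshots), function(i) {
      ens <- run$snapshots[[i]]
      approx_vals <- if (sc$method == "sp") {
        sp_density(ens$x[, 1L], ens$w, sc$sp_eps, sc$shape, density_grid)
      } else {
        eval_density(ens, density_grid)
      }
      ref <- exact_quadratic(rho0, times[i], density_grid, lambda = lambda)
      cbind(data.frame(t = times[i], h = sc$h, dt = sc$dt),
            density_errors(approx_vals, ref, density_grid))
    }))
  }
  res <- list(run = run, ensemble0 = ens0, errors = errors,
              density_grid = density_grid, scenario = sc)
  if (!is.null(outdir)) write_scenario_artifacts(res, outdir)
  res
}

write_scenario_artifacts <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sc <- res$scenario
  run <- res$run
  for (nm in names(run$snapshots)) {
    ens <- run$snapshots[[nm]]
    tab <- data.frame(k = seq_len(n_particles(ens)), x = ens$x[, 1L],
                      omega = ens$w, D = ens$D[1L, 1L, ], h_vol = ens$hvol)
    utils::write.csv(tab, file.path(outdir, sprintf("particles_%s.csv", nm)),
                     row.names = FALSE)
    dtab <- data.frame(x = res$density_grid,
                       rho = eval_density(ens, res$density_grid))
    if (sc$method == "sp") {
      dtab$rho_sp <- sp_density(ens$x[, 1L], ens$w, sc$sp_eps, sc$shape,
                                res$density_grid)
    }
    utils::write.csv(dtab, file.path(outdir, sprintf("density_%s.csv", nm)),
                     row.names = FALSE)
  }
  utils::write.csv(run$log, file.path(outdir, "runlog.csv"), row.names = FALSE)
  if (!is.null(res$errors)) {
    utils::write.csv(res$errors, file.path(outdir, "errors.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ltpagg")),
    fixture = attr(sc$fixture, "name") %||% "custom",
    potential = sc$potential$name, h = sc$h, dt = sc$dt, t_end = sc$t_end,
    shape = sc$shape$name, weights = sc$weights,
    velocity = sc$velocity$strategy, method = sc$method, sp_eps = sc$sp_eps,
    normalize = sc$normalize, jacobian_mode = sc$jacobian_mode,
    blowup_ceiling = sc$blowup_ceiling,
    guard_triggered = run$guard_triggered,
    completed_steps = run$completed_steps
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

#' Convergence study against the exact quadratic solution
#'
#' Repeats a quadratic-potential scenario over a list of spacings `h`, with
#' the time step tied to `h` by `dt_rule` (default the parabolic coupling
#' `dt = h^2/4`), measures \eqn{L^1}, \eqn{L^\infty} and bounded-Lipschitz
#' errors against the closed form at `t_end` on a shared grid resolving the
#' finest run, and fits log-log convergence orders.
#'
#' @param sc a quadratic-potential [scenario()] (its `h` and `dt` are
#'   overridden).
#' @param hs particle spacings (at least 3).
#' @param dt_rule function mapping `h` to the time step.
#' @return A list with `table` (one row per `h`: `h`, `dt`, `l1`, `linf`,
#'   `dbl`) and `orders` (fitted slopes for each error).
#' @export
convergence_study <- function(sc, hs = c(0.2, 0.1, 0.05, 0.025),
                              dt_rule = function(h) h^2 / 4) {
  stopifnot(inherits(sc, "ltp_scenario"))
  if (sc$potential$name != "quadratic") {
    stop("convergence_study requires the quadratic potential (exact solution)")
  }
  if (length(hs) < 3L) stop("need >= 3 resolutions")
  rho0 <- scenario_rho0(sc)
  support <- attr(rho0, "support") %||% c(-1, 1)
  margin <- sc$shape$support_radius * max(hs) + 0.1 * diff(support)
  grid <- seq(support[1] - margin, support[2] + margin, by = min(hs) / 8)
  lambda <- center_of_mass(rho0)
  ref <- exact_quadratic(rho0, sc$t_end, grid, lambda = lambda)
  rows <- lapply(hs, function(h) {
    sch <- sc
    sch$h <- h
    sch$dt <- dt_rule(h)
    ens0 <- scenario_initial_ensemble(sch)
    run <- ltp_run(ens0, sch$potential, sch$velocity, dt = sch$dt,
                   t_end = sch$t_end, blowup_ceiling = Inf,
                   jacobian_mode = sch$jacobian_mode)
    vals <- eval_density(run$final, grid)
    data.frame(h = h, dt = sch$dt,
               l1 = lp_error(vals, ref, 1, grid),
               linf = lp_error(vals, ref, Inf, grid),
               dbl = d_bl_1d(vals, ref, grid))
  })
  tab <- do.call(rbind, rows)
  orders <- list(
    l1 = convergence_order(tab$h, tab$l1)$order,
    linf = convergence_order(tab$h, tab$linf)$order,
    dbl = convergence_order(tab$h, tab$dbl)$order
  )
  list(table = tab, orders = orders)
}

#' Compare LTP and SP reconstructions at matched parameters
#'
#' Runs one quadratic-potential simulation and reconstructs the final
#' density both with the transported LTP shapes and with the fixed-width SP
#' formula from the same positions and weights, reporting \eqn{L^1},
#' \eqn{L^\infty} and \eqn{d_{BL}} errors against the closed form.
#'
#' @param sc a quadratic-potential [scenario()].
#' @param eps SP width (default `sc$sp_eps`, itself defaulting to `h`).
#' @return A two-row `data.frame` (methods `ltp`, `sp`).
#' @export
compare_ltp_sp <- function(sc, eps = NULL) {
  stopifnot(inherits(sc, "ltp_scenario"))
  if (sc$potential$name != "quadratic") {
    stop("compare_ltp_sp requires the quadratic potential (exact solution)")
  }
  eps <- eps %||% sc$sp_eps
  rho0 <- scenario_rho0(sc)
  ens0 <- scenario_initial_ensemble(sc)
  run <- ltp_run(ens0, sc$potential, sc$velocity, dt = sc$dt,
                 t_end = sc$t_end, blowup_ceiling = Inf,
                 jacobian_mode = sc$jacobian_mode)
  support <- attr(rho0, "support") %||% c(-1, 1)
  margin <- sc$shape$support_radius * max(sc$h, eps) + 0.1 * diff(support)
  grid <- seq(support[1] - margin, support[2] + margin, by = sc$h / 8)
  ref <- exact_quadratic(rho0, sc$t_end, grid)
  ltp_vals <- eval_density(run$final, grid)
  sp_vals <- sp_density(run$final$x[, 1L], run$final$w, eps, sc$shape, grid)
  rbind(
    cbind(data.frame(method = "ltp", h = sc$h, eps = NA_real_),
          density_errors(ltp_vals, ref, grid)),
    cbind(data.frame(method = "sp", h = sc$h, eps = eps),
          density_errors(sp_vals, ref, grid))
  )
}
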