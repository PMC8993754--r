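#' Run a quasi-static viscous simulation
#'
#' The time loop tying everything together: at each step the actuator
#' tractions are re-evaluated on the current (deformed) boundary, the
#' quasi-static velocity field is solved, the step size is chosen by a CFL
#' rule, the mesh is advected explicitly (an inverted element rejects the
#' step and halves `dt`, then forces a remesh), element quality triggers a
#' global remesh, and scalar observables are recorded.
#'
#' @param mesh initial `trimesh`.
#' @param material a `material_model`.
#' @param actuators list of `actuator` objects.
#' @param constraints list: `fix` (character labels pinned to zero
#'   velocity) and/or `nullspace = TRUE` for self-equilibrated loading.
#' @param dt_policy list: `cfl` (default 0.2), `dt_max` (default Inf).
#' @param stop list of stop criteria (at least one required): `max_steps`,
#'   `max_time`, `quiescence_tol` (stop when max speed drops below), and/or
#'   `observable` + `threshold` (+ `below = TRUE`): stop once a named
#'   observable crosses the threshold.
#' @param observables named list of functions `f(mesh) -> scalar` recorded
#'   at every step.
#' @param remesh list: `min_quality` triggering a global remesh (default
#'   0.2); `FALSE` disables remeshing.
#' @param snapshot_every record a mesh snapshot every so many steps
#'   (default `Inf`: initial and final only).
#' @param verbose 0 (silent), 1 (per-run summary), 2 (per-step lines).
#' @return a `sim_result`: list with `mesh` (final), `initial_mesh`,
#'   `snapshots` (named by step), `trace` (data.frame: step, time, dt,
#'   vmax, observables), `stopped_by`, `steps`.
#' @export
simulate_morphogenesis <- function(mesh, material, actuators = list(),
                                   constraints = list(fix = character(0)),
                                   dt_policy = list(), stop = list(),
                                   observables = list(),
                                   remesh = list(min_quality = 0.2),
                                   snapshot_every = Inf, verbose = 0) {
  if (length(stop) == 0L)
    stop("simulate_morphogenesis: at least one stop criterion is required")
  cfl <- dt_policy$cfl %||% 0.2
  dt_max <- dt_policy$dt_max %||% Inf
  max_steps <- stop$max_steps %||% 10000L
  max_time <- stop$max_time %||% Inf
  q_tol <- stop$quiescence_tol %||% 0
  min_q <- if (isFALSE(remesh)) 0 else remesh$min_quality %||% 0.2

  dirichlet <- if (length(constraints$fix %||% character(0)) > 0L)
    list(labels = constraints$fix) else NULL
  nullspace <- isTRUE(constraints$nullspace)

  obs_row <- function(m) vapply(observables, function(f) f(m), numeric(1))
  trace <- vector("list", max_steps + 1L)
  trace[[1L]] <- c(step = 0, time = 0, dt = NA_real_, vmax = NA_real_,
                   obs_row(mesh))
  snapshots <- list(`0` = mesh)
  initial_mesh <- mesh
  t_now <- 0; stopped_by <- "max_steps"; nsteps <- 0L

  for (i in seq_len(max_steps)) {
    if (min_q > 0) {
      remeshed <- tryCatch(remesh_if_needed(mesh, min_q),
                           morphosim_halt = function(e) NULL)
      if (is.null(remeshed)) {
        # the advected boundary self-intersected: the simulation cannot
        # continue past contact; report the trace up to this point
        stopped_by <- "boundary_contact"
        break
      }
      mesh <- remeshed
    }
    loads <- withCallingHandlers(
      actuator_loads(mesh, actuators),
      error = function(e) stop("step ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    vel <- solve_velocity(mesh, material, loads = loads,
                          dirichlet = dirichlet, nullspace = nullspace)
    vmax <- max(sqrt(rowSums(unclass(vel)^2)))
    if (vmax <= q_tol) { stopped_by <- "quiescence"; break }
    dt <- cfl_dt(mesh, vel, cfl = cfl, dt_max = dt_max)
    if (is.finite(max_time)) dt <- min(dt, max_time - t_now)
    moved <- NULL
    for (halving in 0:4) {
      moved <- tryCatch(advance_mesh(mesh, vel, dt),
                        morphosim_inversion = function(e) NULL)
      if (!is.null(moved)) break
      dt <- dt / 2
    }
    if (is.null(moved)) {
      mesh <- remesh_if_needed(mesh, 0.99)   # force a clean mesh, re-solve
      next
    }
    mesh <- moved
    t_now <- t_now + dt
    nsteps <- i
    trace[[i + 1L]] <- c(step = i, time = t_now, dt = dt, vmax = vmax,
                         obs_row(mesh))
    if (verbose >= 2)
      message(sprintf("step %d t=%.4g dt=%.3g vmax=%.3g", i, t_now, dt, vmax))
    if (i %% snapshot_every == 0) snapshots[[as.character(i)]] <- mesh
    if (!is.null(stop$observable)) {
      val <- trace[[i + 1L]][[stop$observable]]
      hit <- if (isFALSE(stop$below)) val >= stop$threshold
             else val <= stop$threshold
      if (hit) { stopped_by <- "observable"; break }
    }
    if (t_now >= max_time) { stopped_by <- "max_time"; break }
  }
  snapshots[[as.character(nsteps)]] <- mesh
  trace <- as.data.frame(do.call(rbind, trace[!vapply(trace, is.null, TRUE)]))
  out <- structure(list(mesh = mesh, initial_mesh = initial_mesh,
                        snapshots = snapshots, trace = trace,
                        stopped_by = stopped_by, steps = nsteps),
                   class = "sim_result")
  if (verbose >= 1)
    message(sprintf("run: %d steps, t=%.4g, stopped by %s",
                    nsteps, t_now, stopped_by))
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d steps, final time %.4g, stopped by %s\n",
              x$steps, max(x$trace$time), x$stopped_by))
  cat("  observables:",
      paste(setdiff(names(x$trace), c("step", "time", "dt", "vmax")),
            collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
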