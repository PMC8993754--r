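# Config-driven scenario presets. Each preset is a fully-specified,
# serialisable configuration reproducing one of the morphogenetic
# experiments: wound-ring closure under constant tension or pressure,
# crenel-ear contraction (plain, with dorsal tension gradient, asymmetric,
# soft/slit), mouth invagination, neck flexure (ventral/dorsal), dorsal
# extension, nasal-process growth (linear and quadratic in curvature),
# free normal+tangential boundary stresses, and the placode-nucleated
# buckling bulge. Magnitudes are order-unity model values chosen to land
# each run in its qualitative regime; they are config, not constants.

#' Names of the available scenario presets
#' @return character vector.
#' @export
scenario_names <- function() {
  c("wound_ring_tension", "wound_ring_pressure", "crenel_ear",
    "crenel_ear_gradient", "crenel_ear_asym", "slit_ear", "mouth",
    "mouth_plus_ear", "neck_ventral", "neck_dorsal", "dorsal_extension",
    "nasal_process_linear", "nasal_process_quadratic", "free_morph",
    "buckling_bulge")
}

#' Build a scenario configuration
#'
#' Returns the fully-specified declarative configuration of a preset,
#' optionally overridden field-by-field (`utils::modifyList` semantics).
#' Configurations are plain lists that round-trip through YAML.
#'
#' @param scenario one of `scenario_names()`.
#' @param overrides named list of fields to override.
#' @param seed meshing seed recorded in the config (mesh generation is
#'   fully deterministic; the seed is carried for provenance).
#' @return object of class `scenario_config` (a named list).
#' @export
scenario_config <- function(scenario, overrides = list(), seed = 1L) {
  scenario <- match.arg(scenario, scenario_names())
  base <- list(
    scenario = scenario,
    material = list(E_star = 2, nu_star = 0.45),
    dt = list(cfl = 0.2, dt_max = 1e6),
    remesh = list(min_quality = 0.2),
    seed = as.integer(seed))

  annulus <- list(kind = "annulus", outer_radius = 1, hole_radius = 0.3,
                  target_edge_length = 0.05)
  body <- function(placodes = list(), r = 0, L = 2, H = 1, h = 0.05)
    list(kind = "body", length = L, height = H, placodes = placodes,
         corner_smoothing_radius = r, target_edge_length = h)
  crenel <- function(f = 1) list(position = 1, width = 0.3, depth = 0.2,
                                 shape = "crenel", f = f)
  ear_pair <- function(F = 2, asymmetry = 1)
    list(kind = "shear_pair", label = "ear_base", F = F,
         asymmetry = asymmetry, sense = "contract", normal_T = 0)
  mouth_pair <- function(F = 1.5, asymmetry = 1)
    list(kind = "shear_pair", label = "mouth", F = F, asymmetry = asymmetry,
         sense = "contract", normal_T = 0)

  cfg <- switch(scenario,
    wound_ring_tension = list(
      geometry = annulus,
      actuators = list(list(kind = "line_tension", label = "hole", T = 1)),
      constraints = list(fix = "outer"),
      stop = list(max_steps = 400L, observable = "hole_radius",
                  threshold = 0.1)),
    wound_ring_pressure = list(
      geometry = annulus,
      # matched to the tension preset's initial total force: P = T / r0
      actuators = list(list(kind = "normal_pressure", label = "hole",
                            P = 1 / 0.3)),
      constraints = list(fix = "outer"),
      stop = list(max_steps = 600L, observable = "hole_radius",
                  threshold = 0.1)),
    crenel_ear = list(
      geometry = body(list(crenel())),
      actuators = list(ear_pair()),
      constraints = list(fix = "neck"),
      # contraction followed to 60% of the initial base length: the
      # window over which the self-arrest law stays log-linear before
      # the crenel geometry departs from self-similarity
      stop = list(max_steps = 500L, observable = "base_length",
                  threshold = 0.18)),
    crenel_ear_gradient = list(
      geometry = body(list(crenel())),
      actuators = list(ear_pair(),
                       list(kind = "tension_gradient", label = "ear_crenel",
                            strength = 0.1, direction = c(0, 1))),
      constraints = list(fix = "neck"),
      stop = list(max_steps = 500L, observable = "base_length",
                  threshold = 0.18)),
    crenel_ear_asym = list(
      geometry = body(list(crenel())),
      actuators = list(ear_pair(asymmetry = 0.5)),
      constraints = list(fix = "neck"),
      stop = list(max_steps = 500L, observable = "base_length",
                  threshold = 0.18)),
    slit_ear = list(
      geometry = body(list(crenel(f = 0))),
      actuators = list(ear_pair()),
      constraints = list(fix = "neck"),
      stop = list(max_steps = 600L, observable = "base_length",
                  threshold = 0.12)),
    mouth = list(
      geometry = body(),
      actuators = list(mouth_pair()),
      constraints = list(fix = "neck"),
      stop = list(max_steps = 400L, max_time = 0.6)),
    mouth_plus_ear = list(
      geometry = body(list(crenel())),
      actuators = list(mouth_pair(), ear_pair()),
      constraints = list(fix = "neck"),
      stop = list(max_steps = 400L, max_time = 0.6)),
    neck_ventral = list(
      geometry = body(),
      actuators = list(mouth_pair(),
                       list(kind = "tension_gradient", label = "ventral",
                            strength = 0.5, direction = c(1, 0))),
      constraints = list(fix = "neck"),
      stop = list(max_steps = 400L, max_time = 0.6)),
    neck_dorsal = list(
      geometry = body(),
      actuators = list(mouth_pair(),
                       list(kind = "tension_gradient", label = "dorsal",
                            strength = 0.5, direction = c(1, 0))),
      constraints = list(fix = "neck"),
      stop = list(max_steps = 400L, max_time = 0.6)),
    dorsal_extension = list(
      geometry = body(),
      actuators = list(mouth_pair(),
                       list(kind = "tension_gradient", label = "ventral",
                            strength = 0.3, direction = c(1, 0)),
                       list(kind = "extensional_shear", label = "dorsal",
                            F = 0.5, asymmetry = 1, sense = "extend",
                            normal_T = 0)),
      constraints = list(fix = "neck"),
      stop = list(max_steps = 400L, max_time = 0.6)),
    nasal_process_linear = list(
      geometry = body(r = 0.15, L = 1.2, h = 0.04),
      actuators = list(list(kind = "neg_surface_tension", label = "mouth",
                            gamma = 0.15, m = 1, clamp = TRUE)),
      constraints = list(fix = "neck"),
      stop = list(max_steps = 300L, max_time = 0.5)),
    nasal_process_quadratic = list(
      geometry = body(r = 0.15, L = 1.2, h = 0.04),
      # matched initial tip traction: gamma2 * k0^2 = gamma1 * k0,
      # k0 = 1 / 0.15
      actuators = list(list(kind = "neg_surface_tension", label = "mouth",
                            gamma = 0.15 * 0.15, m = 2, clamp = TRUE)),
      constraints = list(fix = "neck"),
      stop = list(max_steps = 300L, max_time = 0.5)),
    free_morph = list(
      geometry = body(r = 0.15, L = 1.2, h = 0.04),
      actuators = list(list(kind = "normal_pressure", label = "mouth",
                            P = -0.5),
                       list(kind = "tension_gradient", label = "mouth",
                            strength = 0.3, direction = c(0, 1))),
      constraints = list(fix = "neck"),
      stop = list(max_steps = 200L, max_time = 0.5)),
    buckling_bulge = list(
      geometry = body(list(crenel())),
      actuators = list(list(kind = "neg_surface_tension", label = "dorsal",
                            gamma = 0.3, m = 1, clamp = TRUE),
                       ear_pair(F = 1)),
      constraints = list(fix = "neck"),
      stop = list(max_steps = 250L, max_time = 0.6)))

  cfg <- c(base[setdiff(names(base), names(cfg))], cfg)
  cfg <- cfg[c("scenario", "geometry", "material", "actuators",
               "constraints", "dt", "stop", "remesh", "seed")]
  if (length(overrides) > 0L) cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = c("scenario_config", "list"))
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario_config:", x$scenario, "\n")
  cat("  geometry:", x$geometry$kind, " actuators:",
      paste(vapply(x$actuators, `[[`, "", "kind"), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a scenario configuration (YAML)
#'
#' @param config a `scenario_config`.
#' @param path file path.
#' @return `read_scenario_config` returns the `scenario_config`;
#'   `write_scenario_config` returns `path` invisibly. Round-trips are
#'   bit-exact for preset configurations.
#' @export
write_scenario_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = c("scenario_config", "list"))
}

# Build the domain described by a config geometry block.
build_geometry <- function(g) {
  switch(g$kind,
    annulus = build_annulus(g$outer_radius, g$hole_radius,
                            g$target_edge_length),
    body = build_body(g$length, g$height, g$placodes %||% list(),
                      g$corner_smoothing_radius %||% 0,
                      g$target_edge_length),
    stop("unknown geometry kind '", g$kind, "'"))
}

# Scenario-appropriate observables; closures may capture the initial mesh.
scenario_observables <- function(config, mesh0) {
  sc <- config$scenario
  obs <- list()
  if (startsWith(sc, "wound_ring")) {
    act <- config$actuators[[1L]]
    obs$hole_radius <- function(ms) chain_length(ms, "hole") / (2 * pi)
    obs$total_force <- function(ms) {
      cv <- boundary_curvature(ms, "hole")
      ds <- chain_edge_lengths(cv)
      if (act$kind == "line_tension") sum(abs(act$T * cv$kappa) * ds)
      else abs(act$P) * sum(ds)
    }
  }
  if ("ear_base" %in% names(mesh0$chains)) {
    obs$base_length <- function(ms) chain_length(ms, "ear_base")
    obs$ear_area <- function(ms) shape_metrics(ms, placode_outline(ms))$area
    obs$ear_aspect <- function(ms)
      shape_metrics(ms, placode_outline(ms))$aspect_ratio
    obs$ear_iso <- function(ms)
      shape_metrics(ms, placode_outline(ms))$isoperimetric
    obs$ear_centroid_y <- function(ms)
      shape_metrics(ms, placode_outline(ms))$centroid[2]
  }
  if (config$geometry$kind == "body") {
    H <- config$geometry$height
    L <- config$geometry$length
    r <- config$geometry$corner_smoothing_radius %||% 0
    obs$mouth_deflection <- function(ms) chord_deflection(ms, "mouth")
    if (r > 0) {
      ctr <- c(r, H - r)     # centre of the top head-corner arc
      obs$tip_extension <- function(ms) {
        xy <- rbind(chain_all_xy(ms, "mouth"), chain_all_xy(ms, "dorsal"))
        xy <- xy[xy[, 2] > H - 2 * r & xy[, 1] < 4 * r, , drop = FALSE]
        if (nrow(xy) == 0L) return(0)
        max(0, max(sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)) - r)
      }
    }
    # dorsal-profile deviation over the mid-span window (away from the
    # head corner, where corner growth would contaminate the signal)
    obs$dorsal_deviation <- function(ms) {
      xy <- chain_all_xy(ms, "dorsal")
      xy <- xy[xy[, 1] > 0.25 * L & xy[, 1] < 0.92 * L, , drop = FALSE]
      if (nrow(xy) == 0L) return(0)
      max(abs(xy[, 2] - H))
    }
    obs$area <- function(ms) mesh_area(ms)
  }
  obs
}

chain_all_xy <- function(ms, label) {
  ch <- mesh_chain(ms, label)
  ms$vertices[unlist(ch$parts), , drop = FALSE]
}

chain_edge_lengths <- function(cv) {
  n <- nrow(cv)
  ds <- sqrt(diff(cv$x)^2 + diff(cv$y)^2)
  if (isTRUE(attr(cv, "closed")))
    c(ds, sqrt((cv$x[1] - cv$x[n])^2 + (cv$y[1] - cv$y[n])^2))
  else c(ds, 0)
}

#' Run a scenario preset
#'
#' Builds the geometry, material and actuators described by the
#' configuration, runs the simulation, and (optionally) writes the
#' observable trace, boundary polylines, mesh snapshots and a metadata
#' echo to an output directory. Deterministic given the configuration.
#'
#' @param config a `scenario_config` (or a scenario name, for defaults).
#' @param out optional output directory.
#' @param snapshot_every mesh snapshot cadence (default: first/last only).
#' @param verbose passed to the simulation loop.
#' @return a `sim_result` with the `config` attached.
#' @export
run_preset <- function(config, out = NULL, snapshot_every = Inf,
                       verbose = 0) {
  if (is.character(config)) config <- scenario_config(config)
  mesh <- build_geometry(config$geometry)
  soft <- attr(mesh, "softness") %||% c(`1` = 1)
  mat <- material_model(config$material$E_star, config$material$nu_star,
                        softness = soft)
  acts <- lapply(config$actuators, function(a) {
    a <- a[!vapply(a, is.null, TRUE)]
    if (!is.null(a$direction)) a$direction <- unlist(a$direction)
    do.call(actuator, c(list(kind = a$kind, label = a$label),
                        a[setdiff(names(a), c("kind", "label"))]))
  })
  obs <- scenario_observables(config, mesh)
  res <- simulate_morphogenesis(
    mesh, mat, actuators = acts,
    constraints = config$constraints,
    dt_policy = config$dt,
    stop = config$stop,
    observables = obs,
    remesh = config$remesh,
    snapshot_every = snapshot_every,
    verbose = verbose)
  res$config <- config
  if (!is.null(out)) write_run_outputs(res, out)
  res
}
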