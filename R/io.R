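TRAJECTORY_SCHEMA <- "1.0"

#' Save a trajectory archive
#'
#' Stores the full time grid, variational parameters, conservation
#' diagnostics and the resolved configuration in one self-describing,
#' versioned archive, so any observable can be recomputed offline.
#' @param traj a `d1_trajectory`
#' @param path output file (.rds)
#' @param config the resolved configuration list to embed (optional)
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path, config = NULL) {
  obj <- list(schema = TRAJECTORY_SCHEMA, trajectory = traj, config = config,
              diagnostics = conserved_diagnostics(traj))
  saveRDS(obj, path)
  invisible(path)
}

#' Load a trajectory archive written by [write_trajectory()]
#' @param path archive file
#' @return list: `trajectory`, `config`, `diagnostics`, `schema`
#' @export
read_trajectory <- function(path) {
  obj <- readRDS(path)
  major <- function(v) as.integer(strsplit(v, ".", fixed = TRUE)[[1]][1])
  if (is.null(obj$schema) ||
      major(obj$schema) > major(TRAJECTORY_SCHEMA))
    stop("trajectory archive schema ", obj$schema,
         " is newer than supported (", TRAJECTORY_SCHEMA, ")")
  obj
}

#' Export per-ring population time series as TSV
#' @param traj a `d1_trajectory`
#' @param path output file
#' @return `path`, invisibly
#' @export
export_populations <- function(traj, path) {
  pops <- t(ring_populations(traj))
  df <- data.frame(time_fs = traj$times, pops, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

default_config <- function() {
  list(
    schema_version = "1.0",
    geometry = list(layout = "chain", n_rings = 3, shells = 1, spacing = 8.0,
                    n_sites = 16, radius = 2.3, offset_alpha = 10,
                    offset_beta = 170, tilt = 0),
    hamiltonian = list(dipole_strength = 135.88, site_energy = 12500,
                       nn_override = NULL, nnn_override = NULL),
    bath = list(scheme = "linear_dispersion", omega0 = 1670, W = 0.1,
                S = 0.5),
    dynamics = list(initial = "bright", ring = NULL, site = 1, k = 1,
                    t_end = 1000, dt = 0.05, stride_fs = 1,
                    eps = 1e-12, norm_tol = 1e-3),
    observables = list(msd_window = c(20, 600), crossover = TRUE)
  )
}

merge_config <- function(user, base) {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stop("unknown configuration key: ", nm)
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(user[[nm]], base[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  merge_config(config, default_config())
}

#' Run a full quantum simulation from a configuration
#'
#' Executes geometry -> Hamiltonian -> bath -> initial state -> propagation
#' -> observables from one configuration (a nested list or a YAML file
#' path; unknown keys are rejected). The returned object embeds the fully
#' resolved configuration, so every output is reproducible from it alone.
#'
#' @param config nested list or YAML path; see `excitonsim:::default_config()`
#'   for the schema and defaults
#' @param verbose print a structured log of parameters and diagnostics
#' @return list: `trajectory`, `populations`, `msd`, `delocalization`
#'   (L_rho and L_s traces), `fit` (diffusion-exponent fit), `config`,
#'   `diagnostics`
#' @export
run_simulation <- function(config = list(), verbose = FALSE) {
  cfg <- resolve_config(config)
  g <- cfg$geometry
  ring <- build_b850_ring(n_sites = g$n_sites, radius = g$radius,
                          offset_alpha = g$offset_alpha,
                          offset_beta = g$offset_beta, tilt = g$tilt,
                          site_energy = cfg$hamiltonian$site_energy)
  geom <- if (g$layout == "chain")
    build_nanoarray("chain", n_rings = g$n_rings, spacing = g$spacing,
                    ring_template = ring)
  else
    build_nanoarray("hexagonal", shells = g$shells, spacing = g$spacing,
                    ring_template = ring)
  H <- coupling_matrix(geom, dipole_strength = cfg$hamiltonian$dipole_strength,
                       site_energy = cfg$hamiltonian$site_energy,
                       nn_override = cfg$hamiltonian$nn_override,
                       nnn_override = cfg$hamiltonian$nnn_override)
  b <- cfg$bath
  bath <- make_bath(b$scheme, omega0 = b$omega0, W = b$W, S = b$S,
                    n_sites = g$n_sites)
  dy <- cfg$dynamics
  ring0 <- if (is.null(dy$ring)) geom$central_ring else dy$ring
  st <- initial_state(H, bath, kind = dy$initial, ring = ring0,
                      k = dy$k, site = dy$site)
  if (verbose)
    message(sprintf("propagating %d rings x %d sites for %g fs (dt = %g fs)",
                    H$n_rings, H$n_sites_per_ring, dy$t_end, dy$dt))
  traj <- propagate(st, H, bath, t_end = dy$t_end, dt = dy$dt,
                    stride_fs = dy$stride_fs, eps = dy$eps,
                    norm_tol = dy$norm_tol)
  pops <- ring_populations(traj)
  msd <- msd_trace(traj, origin_ring = ring0)
  deloc <- delocalization_trace(traj)
  ow <- cfg$observables
  fit <- tryCatch(
    diffusion_exponent(msd$time, msd$msd,
                       window = c(ow$msd_window[1],
                                  min(ow$msd_window[2], dy$t_end)),
                       crossover = isTRUE(ow$crossover)),
    error = function(e) NULL)
  diag <- conserved_diagnostics(traj)
  if (verbose)
    message(sprintf("norm drift %.2e | energy drift %.2e | gamma = %s",
                    diag$norm_drift, diag$energy_drift,
                    if (is.null(fit)) "NA" else sprintf("%.3f", fit$gamma)))
  list(trajectory = traj, populations = pops, msd = msd,
       delocalization = deloc, fit = fit, config = cfg, diagnostics = diag)
}

default_master_config <- function() {
  list(
    schema_version = "1.0",
    model = list(K = 1e-3, k = 0.1, a = 8, layout = "chain",
                 n_rings = 4001, extent = 25),
    laser = list(sigma = 169.86, A0 = 1, center = NULL),
    mode = "stationary",        # or "dynamics"
    times = c(1, 10, 100)
  )
}

#' Run the classical hopping model from a configuration
#'
#' @param config nested list or YAML path with blocks `model`, `laser`,
#'   `mode` ("stationary" or "dynamics") and `times` (ps, for dynamics)
#' @return for stationary mode: the [stationary_1d()]/[stationary_2d()]
#'   result plus `Ld` diagnostics; for dynamics: list with the
#'   laser-prepared `p0` and fields at the requested times
#' @export
run_master_eq <- function(config = list()) {
  cfg <- merge_config(if (is.character(config)) yaml::read_yaml(config)
                      else config, default_master_config())
  m <- cfg$model
  model <- hopping_model(K = m$K, k = m$k, a = m$a, layout = m$layout,
                         n_rings = m$n_rings, extent = m$extent)
  laser <- laser_profile(sigma = cfg$laser$sigma, A0 = cfg$laser$A0,
                         center = cfg$laser$center)
  if (cfg$mode == "stationary") {
    if (laser$A0 == 0) {
      n <- if (m$layout == "chain") m$n_rings else (2 * m$extent + 1)^2
      return(list(p = numeric(n), Ld = NULL, config = cfg))
    }
    st <- if (m$layout == "chain") stationary_1d(model, laser)
          else stationary_2d(model, laser)
    ld <- if (m$layout == "chain") diffusion_length(st, laser) else NULL
    c(st, list(Ld = ld, config = cfg))
  } else {
    p0 <- initial_excitation(model, laser)
    fields <- lapply(cfg$times, function(t)
      if (m$layout == "chain") dynamics_1d(p0, model, t)
      else dynamics_2d(p0, model, t))
    list(p0 = p0, times = cfg$times, fields = fields, config = cfg)
  }
}

#' Deterministic toy fixtures used across examples and tests
#'
#' Registry of small systems: `"dimer"` (2-site exciton with analytic
#' splitting), `"ring1"` (one default B850 ring plus bath), `"chain3"` and
#' `"chain11"` (1D nanoarrays), `"hex7"` (seven-ring hexagonal array),
#' `"fbm_h05"` (seeded fractional Brownian motion, H = 0.5) and
#' `"rate_grid_small"` (a 21-ring hopping model with laser).
#'
#' @param name fixture name; an unknown name raises an error listing the
#'   registry
#' @return the fixture object (structure depends on the fixture)
#' @export
fixture_suite <- function(name) {
  registry <- list(
    dimer = function() {
      ring <- build_b850_ring(n_sites = 2, radius = 0.5, offset_alpha = 0,
                              offset_beta = 0, site_energy = 12000)
      geom <- build_nanoarray("chain", n_rings = 1, ring_template = ring)
      H <- coupling_matrix(geom, dipole_strength = 100, site_energy = 12000)
      list(geom = geom, H = H,
           splitting = 2 * abs(H$J[1, 2]))
    },
    ring1 = function() {
      geom <- build_nanoarray("chain", n_rings = 1)
      list(geom = geom, H = coupling_matrix(geom),
           bath = make_bath("linear_dispersion"))
    },
    chain3 = function() {
      geom <- build_nanoarray("chain", n_rings = 3)
      list(geom = geom, H = coupling_matrix(geom),
           bath = make_bath("linear_dispersion"))
    },
    chain11 = function() {
      geom <- build_nanoarray("chain", n_rings = 11)
      list(geom = geom, H = coupling_matrix(geom),
           bath = make_bath("linear_dispersion"))
    },
    hex7 = function() {
      geom <- build_nanoarray("hexagonal", shells = 1)
      list(geom = geom, H = coupling_matrix(geom),
           bath = make_bath("linear_dispersion"))
    },
    fbm_h05 = function() fbm_generator(0.5, 4096, seed = 1405),
    rate_grid_small = function() {
      list(model = hopping_model(K = 0.01, k = 0.1, a = 8, layout = "chain",
                                 n_rings = 21),
           laser = laser_profile(sigma = 24, center = 11))
    }
  )
  if (!name %in% names(registry))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(registry), collapse = ", "))
  registry[[name]]()
}
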