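#' Langevin integrator parameters
#'
#' @param dt Timestep, ps (default 0.01 ps = 10 fs, the usual choice for
#'   residue-level coarse-grained models).
#' @param friction Langevin friction, 1/ps.
#' @param temperature Target temperature, K.
#' @param seed Integer RNG seed.
#' @return List of class `integrator_params`.
#' @export
integrator_params <- function(dt = 0.01, friction = 0.01, temperature = 300, seed = 1) {
  stopifnot(dt > 0, friction >= 0)
  structure(list(dt = dt, friction = friction, temperature = temperature,
                 seed = as.integer(seed)),
            class = "integrator_params")
}

#' Barostat parameters (isotropic weak coupling)
#'
#' Berendsen-style isotropic volume rescaling toward a target pressure, used
#' for bulk NPT stability runs (the coexistence protocol targets P = 0).
#' Slab systems are never pressure-coupled.
#'
#' @param pressure Target pressure in model units (kJ/mol/nm^3); 0 for the
#'   condensate-stability protocol.
#' @param coupling_time Coupling time, ps; must exceed the timestep.
#' @param compressibility Coupling compressibility (nm^3 mol/kJ), sets the
#'   rescaling strength.
#' @return List of class `barostat_params`.
#' @export
barostat_params <- function(pressure = 0, coupling_time = 1, compressibility = 0.05) {
  stopifnot(coupling_time > 0, compressibility > 0)
  structure(list(pressure = pressure, coupling_time = coupling_time,
                 compressibility = compressibility, isotropic = TRUE),
            class = "barostat_params")
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param topology A `cg_topology`.
#' @param temperature K.
#' @return n x 3 velocity matrix (nm/ps) with the centre-of-mass drift removed.
#' @export
init_velocities <- function(topology, temperature) {
  m <- topology$beads$mass
  v <- matrix(rnorm(3 * length(m)), ncol = 3) * sqrt(.kB * temperature / m)
  sweep(v, 2, colSums(v * m) / sum(m))
}

run_engine <- function(system, params, n_steps, thin, state = NULL,
                       velocities = NULL, npt = FALSE,
                       barostat = barostat_params(), t_offset = 0,
                       reseed = TRUE) {
  topo <- system$topology; cfg <- system$config
  if (reseed) set.seed(params$seed)
  if (is.null(velocities)) velocities <- init_velocities(topo, params$temperature)
  ang <- structured_angle_triplets(topo, state)
  scale <- ledger_pair_scale(topo, state)
  larks_id <- topo$beads$larks_instance
  larks_id[is.na(larks_id)] <- 0L
  kappa <- if (is.finite(system$dh$debye_length)) 1 / system$dh$debye_length else 0
  res <- cg_run_cpp(cfg$positions, velocities, cfg$box,
                    topo$beads$chain, topo$beads$sigma, topo$beads$lambda,
                    topo$beads$charge, topo$beads$mass,
                    topo$bonds, system$bonded$bond_length, system$bonded$bond_k,
                    ang, system$bonded$angle_theta0, system$bonded$angle_k,
                    system$table$eps_ah, system$table$cutoff_ah, system$table$cutoff_dh,
                    system$dh$bjerrum_prefactor, kappa,
                    as.integer(larks_id), scale,
                    as.integer(n_steps), params$dt, params$friction,
                    params$temperature, .kB, as.integer(thin),
                    npt, barostat$pressure, barostat$coupling_time,
                    barostat$compressibility, t_offset)
  nf <- res$n_frames
  structure(list(
    time = res$frames_time[seq_len(nf)],
    frames = res$frames_pos[seq_len(nf)],
    box = res$frames_box[seq_len(nf), , drop = FALSE],
    temperature = res$frames_T[seq_len(nf)],
    energy = res$frames_E[seq_len(nf)],
    pressure = res$frames_P[seq_len(nf), , drop = FALSE],
    final = list(positions = res$positions, velocities = res$velocities, box = res$box),
    diverged = res$diverged,
    params = params, topology_mass = topology_mass(system$topology)),
    class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("<cg_trajectory> %d frames, t = %.1f..%.1f ps, <T> = %.1f K%s\n",
              length(x$time), min(x$time), max(x$time), mean(x$temperature),
              if (isTRUE(x$diverged)) " [volume diverged]" else ""))
  invisible(x)
}

#' Per-frame summary of a trajectory
#'
#' @param traj A `cg_trajectory`.
#' @return Tibble with time (ps), instantaneous temperature (K), total energy
#'   (kJ/mol), scalar virial pressure (kJ/mol/nm^3) and mass density (g/L).
#' @export
trajectory_summary <- function(traj) {
  vol <- apply(traj$box, 1, prod)
  tibble::tibble(
    time = traj$time, temperature = traj$temperature, energy = traj$energy,
    pressure = rowMeans(traj$pressure[, 1:3, drop = FALSE]),
    density = traj$topology_mass * .dens_conv / vol)
}

#' Relax a freshly built configuration
#'
#' Displacement-capped steepest descent on the potential energy, removing the
#' residue overlaps a random-walk packing leaves behind so that dynamics can
#' start at the production timestep.
#'
#' @param system A [cg_system()].
#' @param state Optional LARKS ledger.
#' @param max_steps Iteration cap.
#' @param max_disp Largest per-bead displacement per iteration (nm).
#' @param tol Stop when the largest force falls below this (kJ/mol/nm).
#' @return The system with relaxed coordinates.
#' @export
minimize_config <- function(system, state = NULL, max_steps = 200,
                            max_disp = 0.02, tol = 100) {
  cfg <- system$config
  for (it in seq_len(max_steps)) {
    ef <- total_energy_forces(cfg, system$topology, system$table, system$dh,
                              state, system$bonded)
    fmax <- max(abs(ef$forces))
    if (fmax < tol) break
    step <- min(max_disp / fmax, 1e-4)
    cfg$positions <- cfg$positions + step * ef$forces
  }
  system$config <- cfg
  system
}

#' Single Langevin (BAOAB) step
#'
#' One update of the splitting integrator; mainly a building block for tests
#' and custom drivers — the runners integrate whole trajectories in compiled
#' code.
#'
#' @param system A [cg_system()].
#' @param params [integrator_params()].
#' @param velocities Optional n x 3 start velocities (default: zero).
#' @param state Optional LARKS ledger.
#' @return List with updated `config` and `velocities`.
#' @export
langevin_step <- function(system, params, velocities = NULL, state = NULL) {
  if (is.null(velocities)) velocities <- matrix(0, system$topology$n_beads, 3)
  res <- run_engine(system, params, n_steps = 1, thin = 1, state = state,
                    velocities = velocities, reseed = FALSE)
  cfg <- system$config
  cfg$positions <- res$final$positions
  list(config = cfg, velocities = res$final$velocities)
}

#' Run canonical (NVT) Langevin dynamics
#'
#' Fixed box, Langevin thermostat. An optional hook is invoked every
#' `hook_interval` steps with the instantaneous configuration (this is the
#' entry point the ageing engine uses).
#'
#' @param system A [cg_system()].
#' @param params [integrator_params()].
#' @param n_steps Number of steps.
#' @param thin Record a frame every `thin` steps.
#' @param state Optional LARKS ledger (activates structured interactions).
#' @param hook Optional `function(config, time)` side-effect callback.
#' @param hook_interval Steps between hook calls.
#' @return A `cg_trajectory`.
#' @export
run_nvt <- function(system, params, n_steps, thin = 100, state = NULL,
                    hook = NULL, hook_interval = 1000) {
  if (is.null(hook)) return(run_engine(system, params, n_steps, thin, state = state))
  set.seed(params$seed)
  vel <- init_velocities(system$topology, params$temperature)
  n_chunks <- floor(n_steps / hook_interval)
  pieces <- vector("list", n_chunks)
  for (ch in seq_len(n_chunks)) {
    tr <- run_engine(system, params, hook_interval, thin, state = state,
                     velocities = vel, t_offset = (ch - 1) * hook_interval * params$dt,
                     reseed = FALSE)
    system$config$positions <- tr$final$positions
    vel <- tr$final$velocities
    hook(system$config, ch * hook_interval * params$dt)
    pieces[[ch]] <- tr
  }
  bind_trajectories(pieces)
}

bind_trajectories <- function(pieces) {
  out <- pieces[[length(pieces)]]
  out$time <- unlist(lapply(pieces, `[[`, "time"))
  out$frames <- do.call(c, lapply(pieces, `[[`, "frames"))
  out$box <- do.call(rbind, lapply(pieces, `[[`, "box"))
  out$temperature <- unlist(lapply(pieces, `[[`, "temperature"))
  out$energy <- unlist(lapply(pieces, `[[`, "energy"))
  out$pressure <- do.call(rbind, lapply(pieces, `[[`, "pressure"))
  out$diverged <- any(vapply(pieces, `[[`, logical(1), "diverged"))
  out
}

#' Run isothermal-isobaric (NPT) dynamics
#'
#' Bulk (cubic) configurations only: Langevin thermostat plus isotropic
#' weak-coupling volume rescaling toward the barostat target. A volume
#' divergence beyond 10x the initial volume raises the instability flag that
#' the phase-diagram protocol reads as "evolves into the diluted phase".
#'
#' @inheritParams run_nvt
#' @param barostat [barostat_params()].
#' @return A `cg_trajectory` carrying `diverged` and a `density` series via
#'   [trajectory_summary()].
#' @export
run_npt <- function(system, params, barostat = barostat_params(),
                    n_steps = 10000, thin = 100, state = NULL) {
  run_engine(system, params, n_steps, thin, state = state,
             npt = TRUE, barostat = barostat)
}

#' Classify the stability of an NPT run
#'
#' A run is `"condensed"` if the mean density over its final quarter is at
#' least 50% of the initial density; `"diluted"` if the volume diverged or the
#' final-quarter density dropped below 10% of the initial; `"marginal"`
#' otherwise (treated as not stable by the bracketing protocol).
#'
#' @param traj `cg_trajectory` from [run_npt()].
#' @return Character scalar: `"condensed"`, `"diluted"` or `"marginal"`.
#' @export
classify_stability <- function(traj) {
  s <- trajectory_summary(traj)
  rho0 <- s$density[1]
  rho_end <- mean(tail(s$density, max(1, floor(nrow(s) / 4))))
  if (isTRUE(traj$diverged) || rho_end < 0.1 * rho0) return("diluted")
  if (rho_end >= 0.5 * rho0) return("condensed")
  "marginal"
}

#' Write a trajectory as plain XYZ with a JSON sidecar
#'
#' One XYZ block per frame (element = residue code); metadata (units, box per
#' frame, seed, integrator parameters) goes to `<path>.json`.
#'
#' @param traj A `cg_trajectory`.
#' @param topology The matching `cg_topology`.
#' @param path Output `.xyz` path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  codes <- topology$beads$code
  for (f in seq_along(traj$frames)) {
    p <- traj$frames[[f]]
    writeLines(as.character(nrow(p)), con)
    writeLines(sprintf("t= %.4f ps", traj$time[f]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", codes, p[, 1], p[, 2], p[, 3]), con)
  }
  jsonlite::write_json(list(units = list(length = "nm", time = "ps"),
                            n_frames = length(traj$frames),
                            box = traj$box, time = traj$time,
                            seed = traj$params$seed,
                            dt = traj$params$dt, friction = traj$params$friction,
                            temperature = traj$params$temperature),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
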