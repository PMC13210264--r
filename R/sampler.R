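# Langevin dynamics (BAOAB splitting) over the Go potential, plus the
# unfolded-ensemble protocol and Q-terminated folding runs.

#' Create a simulation state
#'
#' @param positions coordinate matrix (angstrom), one row per atom.
#' @param structure the [go_structure()] the state belongs to (supplies
#'   masses for velocity initialization).
#' @param velocities optional velocity matrix (angstrom/ps); when `NULL`,
#'   Maxwell-Boltzmann velocities at `temperature` are drawn with `seed`.
#' @param temperature target temperature (K).
#' @param seed integer seed recorded with the state.
#' @param time simulation time offset (ps).
#' @return A `go_state` list.
#' @export
simulation_state <- function(positions, structure, velocities = NULL,
                             temperature = 353, seed = 1L, time = 0) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == nrow(structure$atoms))
  if (is.null(velocities)) {
    velocities <- maxwell_velocities(structure$atoms$mass, temperature, seed)
  }
  stopifnot(nrow(velocities) == nrow(positions))
  structure(
    list(positions = positions, velocities = as.matrix(velocities),
         time = time, seed = as.integer(seed), temperature = temperature),
    class = "go_state"
  )
}

#' Maxwell-Boltzmann velocities
#'
#' @param masses atomic masses (amu).
#' @param temperature K.
#' @param seed RNG seed.
#' @return velocity matrix (angstrom/ps).
#' @export
maxwell_velocities <- function(masses, temperature, seed) {
  set.seed(seed)
  kfac <- 418.4
  sd <- sqrt(kB * temperature * kfac / masses)
  matrix(stats::rnorm(3 * length(masses), 0, rep(sd, 3)),
         ncol = 3)
}

.check_dt <- function(dt, structure, params) {
  # stiffest bond: V = k (r-r0)^2 has omega = sqrt(2 k kfac (1/mi + 1/mj))
  kfac <- 418.4
  b <- structure$bonds
  m <- structure$atoms$mass
  invmu <- 1 / m[b[, 1]] + 1 / m[b[, 2]]
  omega_max <- sqrt(2 * params$k_bond * kfac * max(invmu))
  if (dt > 0.2 * 2 * pi / omega_max) {
    stop("dt = ", dt, " ps is unstable for the stiffest bond (limit ",
         signif(0.2 * 2 * pi / omega_max, 3), " ps)")
  }
  invisible(TRUE)
}

#' Run BAOAB Langevin dynamics
#'
#' A single-trajectory integration at the target temperature. With
#' `friction = 0` the update reduces to velocity Verlet (NVE). The same
#' `(seed, parameters)` pair reproduces the trajectory exactly.
#'
#' @param state a [simulation_state()].
#' @param structure,cmap,params the system: structure, its native contact
#'   map and [go_parameters()].
#' @param n_steps number of integration steps.
#' @param dt timestep (ps); default 2 fs.
#' @param friction Langevin friction (1/ps).
#' @param temperature target temperature (K); defaults to the state's.
#' @param seed seed for the thermostat noise; defaults to the state's.
#' @param stride steps between Q-based termination checks.
#' @param record_stride steps between stored frames.
#' @param q_stop terminate once Q exceeds this value (NULL disables).
#' @param q_stop_low terminate once Q falls to or below this value
#'   (NULL disables).
#' @return A `go_trajectory`: list of `frames` (coordinate matrices),
#'   `times` (ps), `q`, `epot`, `ekin` (kcal/mol), `final_state`,
#'   `outcome` (one of `"max_steps"`, `"folded"`,
#'   `"unfolded_target_reached"`) and `metadata`.
#' @export
langevin_run <- function(state, structure, cmap, params = go_parameters(),
                         n_steps, dt = 0.002, friction = 1,
                         temperature = state$temperature,
                         seed = state$seed, stride = 100,
                         record_stride = stride, q_stop = NULL,
                         q_stop_low = NULL) {
  .check_dt(dt, structure, params)
  sys <- .cpp_system(structure, cmap, params)
  res <- cpp_langevin_run(
    state$positions, state$velocities, structure$atoms$mass, sys,
    as.integer(n_steps), dt, friction, temperature, as.integer(seed),
    as.integer(stride), params$lambda_formed,
    if (is.null(q_stop)) -1 else q_stop,
    if (is.null(q_stop_low)) -1 else q_stop_low,
    as.integer(record_stride)
  )
  n <- nrow(state$positions)
  frames <- lapply(seq_len(nrow(res$frames)), function(r) {
    matrix(res$frames[r, ], n, 3, byrow = TRUE)
  })
  outcome <- c("max_steps", "folded", "unfolded_target_reached")[res$outcome + 1]
  structure(
    list(
      frames = frames, times = res$times + state$time, q = res$q,
      epot = res$epot, ekin = res$ekin,
      final_state = simulation_state(res$positions, structure,
                                     velocities = res$velocities,
                                     temperature = temperature, seed = seed,
                                     time = state$time + res$steps * dt),
      outcome = outcome, steps = res$steps,
      metadata = list(seed = as.integer(seed), temperature = temperature,
                      dt = dt, friction = friction, stride = stride,
                      record_stride = record_stride,
                      parameter_hash = rlang::hash(params))
    ),
    class = "go_trajectory"
  )
}

#' @export
print.go_trajectory <- function(x, ...) {
  cat("Go-model trajectory: ", length(x$frames), " frames over ",
      x$steps, " steps at ", x$metadata$temperature, " K (outcome: ",
      x$outcome, ", final Q = ", round(x$q[length(x$q)], 3), ")\n",
      sep = "")
  invisible(x)
}

.spawn_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate an ensemble of unfolded configurations
#'
#' Each configuration is seeded with a self-avoiding geometric
#' randomization (zero formed native contacts by construction, see
#' [randomize_unfolded()]) and then equilibrated with high-temperature
#' Langevin dynamics at a temperature drawn uniformly from `T_range`; the
#' last visited zero-contact frame is returned. A configuration that never
#' revisits zero formed contacts during equilibration is an error that
#' reports the best (lowest) Q reached.
#'
#' @param structure,cmap,params the system.
#' @param n_configs number of unfolded configurations.
#' @param T_range unfolding temperature range (K).
#' @param seed master seed; per-configuration seeds are spawned from it.
#' @param n_equil_steps high-temperature equilibration steps.
#' @param dt,friction,stride integrator settings.
#' @return list of `go_state` objects, each with `Q = 0` under the
#'   formation criterion and metadata attributes `temperature` and `seed`.
#' @export
generate_unfolded_ensemble <- function(structure, cmap,
                                       params = go_parameters(),
                                       n_configs, T_range = c(550, 700),
                                       seed = 1L, n_equil_steps = 20000,
                                       dt = 0.002, friction = 1,
                                       stride = 100) {
  stopifnot(n_configs >= 1)
  seeds <- .spawn_seeds(seed, 2 * n_configs)
  set.seed(seed)
  temps <- stats::runif(n_configs, T_range[1], T_range[2])
  out <- vector("list", n_configs)
  for (k in seq_len(n_configs)) {
    pos <- randomize_unfolded(structure, seed = seeds[k], cmap = cmap,
                              lambda_formed = params$lambda_formed)
    st <- simulation_state(pos, structure, temperature = temps[k],
                           seed = seeds[n_configs + k])
    if (n_equil_steps > 0) {
      tr <- langevin_run(st, structure, cmap, params,
                         n_steps = n_equil_steps, dt = dt,
                         friction = friction, temperature = temps[k],
                         seed = seeds[n_configs + k], stride = stride,
                         record_stride = stride)
      zero <- which(tr$q == 0)
      if (length(zero) == 0) {
        stop("configuration ", k, " never revisited zero formed contacts ",
             "during equilibration; best Q reached: ", min(tr$q))
      }
      pos <- tr$frames[[max(zero)]]
    }
    st <- simulation_state(pos, structure, temperature = temps[k],
                           seed = seeds[n_configs + k])
    attr(st, "unfold_temperature") <- temps[k]
    out[[k]] <- st
  }
  out
}

#' Run a folding simulation until Q exceeds the folding threshold
#'
#' Starts from an unfolded configuration (Q < 0.2 required) and integrates
#' at the folding temperature until over `q_stop` of all native contacts
#' are formed, or the step budget is exhausted.
#'
#' @param start a `go_state` with Q < 0.2.
#' @param structure,cmap,params the system.
#' @param temperature folding temperature (K); default 353.
#' @param q_stop folding threshold on Q (default 0.8).
#' @param max_steps step budget.
#' @param seed thermostat seed.
#' @param dt,friction,stride,record_stride integrator settings.
#' @return A `go_trajectory` with outcome `"folded"` or `"max_steps"`.
#' @export
run_folding <- function(start, structure, cmap, params = go_parameters(),
                        temperature = 353, q_stop = 0.8, max_steps,
                        seed = start$seed, dt = 0.002, friction = 1,
                        stride = 100, record_stride = stride) {
  q0 <- compute_q(start$positions, cmap,
                  lambda_formed = params$lambda_formed)
  if (q0 >= 0.2) {
    stop("start configuration has Q = ", round(q0, 3),
         "; folding runs must start from an unfolded state (Q < 0.2)")
  }
  st <- simulation_state(start$positions, structure,
                         temperature = temperature, seed = seed,
                         time = start$time)
  langevin_run(st, structure, cmap, params, n_steps = max_steps, dt = dt,
               friction = friction, temperature = temperature, seed = seed,
               stride = stride, record_stride = record_stride,
               q_stop = q_stop)
}

#' Write a trajectory as a multi-model PDB with a metadata sidecar
#'
#' Frames become successive MODEL/ENDMDL blocks of one PDB file; the
#' run metadata (seed, temperature, timestep, friction, stride,
#' parameter hash, outcome) and the recorded Q series go to a JSON
#' sidecar next to it (`<path>.json`).
#'
#' @param trajectory a `go_trajectory`.
#' @param structure the [go_structure()] the frames belong to.
#' @param path output PDB path.
#' @return invisibly, the sidecar path.
#' @export
write_trajectory <- function(trajectory, structure, path) {
  tmp <- tempfile(fileext = ".pdb")
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (k in seq_along(trajectory$frames)) {
    write_frame(structure, trajectory$frames[[k]], tmp)
    lines <- readLines(tmp)
    lines <- lines[!grepl("^END$", lines)]
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  unlink(tmp)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    c(trajectory$metadata,
      list(outcome = trajectory$outcome, steps = trajectory$steps,
           times = trajectory$times, q = trajectory$q)),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}
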