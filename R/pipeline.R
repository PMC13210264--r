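# End-to-end orchestration: prepare -> unfold -> fold -> analyze -> report
# for one or two (unmodified/modified) systems, with per-stage outputs and
# a manifest that suffices to reproduce the run.

#' Build a pipeline run configuration
#'
#' @param structure a [go_structure()] or a PDB file path.
#' @param domains a `go_domains`, a named list of ranges, or a domain
#'   config file path.
#' @param modification optional residue index receiving the m2,2G
#'   modification; when set, both the unmodified and the modified system
#'   are run and compared.
#' @param n_trajectories folding trajectories per system.
#' @param t_unfold unfolding temperature range (K).
#' @param t_fold folding temperature (K).
#' @param max_steps step budget per folding trajectory.
#' @param q_stop folding threshold on Q.
#' @param params a [go_parameters()].
#' @param master_seed master seed; all stage seeds derive from it.
#' @param out_dir output directory (created if missing).
#' @param dt,friction,stride,record_stride integrator settings.
#' @param n_bins bins for F(Q).
#' @param unfold_method `"high_t"` (geometric seed + high-temperature
#'   equilibration) or `"random"` (geometric randomization only).
#' @param n_equil_steps high-temperature equilibration steps.
#' @return A `go_run_config` list.
#' @export
go_run_config <- function(structure, domains, modification = NULL,
                          n_trajectories = 60, t_unfold = c(550, 700),
                          t_fold = 353, max_steps = 3e5, q_stop = 0.8,
                          params = go_parameters(), master_seed = 1L,
                          out_dir = tempfile("gofold_run_"),
                          dt = 0.002, friction = 1, stride = 100,
                          record_stride = 500, n_bins = 20,
                          unfold_method = c("high_t", "random"),
                          n_equil_steps = 20000) {
  if (is.character(structure)) structure <- read_structure(structure)
  if (!inherits(domains, "go_domains")) {
    domains <- assign_domains(structure, domains)
  }
  stopifnot(n_trajectories >= 1)
  structure(
    list(structure = structure, domains = domains,
         modification = modification, n_trajectories = n_trajectories,
         t_unfold = t_unfold, t_fold = t_fold, max_steps = max_steps,
         q_stop = q_stop, params = params,
         master_seed = as.integer(master_seed), out_dir = out_dir,
         dt = dt, friction = friction, stride = stride,
         record_stride = record_stride, n_bins = n_bins,
         unfold_method = match.arg(unfold_method),
         n_equil_steps = n_equil_steps),
    class = "go_run_config"
  )
}

.run_one_system <- function(tag, structure, cmap, config, seed) {
  out <- file.path(config$out_dir, tag)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  params <- config$params
  domains <- config$domains
  write_contact_map(cmap, file.path(out, "contact_map.tsv"))
  write_frame(structure, structure$xyz, file.path(out, "native.pdb"))

  seeds <- .spawn_seeds(seed, 2 * config$n_trajectories + 1)
  # unfolded ensemble
  if (config$unfold_method == "high_t") {
    starts <- generate_unfolded_ensemble(
      structure, cmap, params, n_configs = config$n_trajectories,
      T_range = config$t_unfold, seed = seeds[1],
      n_equil_steps = config$n_equil_steps, dt = config$dt,
      friction = config$friction, stride = config$stride
    )
  } else {
    starts <- lapply(seq_len(config$n_trajectories), function(k) {
      pos <- randomize_unfolded(structure, seed = seeds[k + 1], cmap = cmap,
                                lambda_formed = params$lambda_formed)
      simulation_state(pos, structure, temperature = config$t_fold,
                       seed = seeds[k + 1])
    })
  }

  # folding runs + per-trajectory analyses
  trajs <- vector("list", config$n_trajectories)
  series <- vector("list", config$n_trajectories)
  labels <- character(config$n_trajectories)
  outcomes <- character(config$n_trajectories)
  for (k in seq_len(config$n_trajectories)) {
    sk <- seeds[config$n_trajectories + 1 + k]
    tr <- run_folding(starts[[k]], structure, cmap, params,
                      temperature = config$t_fold, q_stop = config$q_stop,
                      max_steps = config$max_steps, seed = sk,
                      dt = config$dt, friction = config$friction,
                      stride = config$stride,
                      record_stride = config$record_stride)
    qs <- q_series(tr, cmap, domains, lambda_formed = params$lambda_formed)
    trajs[[k]] <- tr
    series[[k]] <- qs
    labels[k] <- classify_pathway(qs)$label
    outcomes[k] <- tr$outcome
    utils::write.table(
      round(qs, 6), file.path(out, sprintf("q_series_%03d.tsv", k)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }

  # pooled analyses
  q_all <- unlist(lapply(series, function(x) x$q))
  fq <- free_energy_profile(q_all, config$t_fold, n_bins = config$n_bins)
  utils::write.table(
    data.frame(q_mid = fq$bin_mid, F_kcal_mol = round(fq$F, 6),
               occupancy = fq$occupancy),
    file.path(out, "free_energy_profile.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  qt <- unlist(lapply(series, function(x) x$q_tsl))
  qd <- unlist(lapply(series, function(x) x$q_dsl))
  hist2d <- NULL
  if (!is.null(qt) && !is.null(qd)) {
    hist2d <- q2d_histogram(qt, qd)
    utils::write.table(hist2d$counts,
                       file.path(out, "q_tsl_dsl_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  freq <- contact_frequency_map(
    do.call(c, lapply(trajs, `[[`, "frames")), cmap,
    n_residues = nrow(structure$residues),
    lambda_formed = params$lambda_formed
  )
  utils::write.table(round(freq, 4),
                     file.path(out, "contact_frequency_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  summ <- pathway_fractions(labels)
  jsonlite::write_json(
    list(labels = summ$labels, fractions = summ$fractions,
         counts = summ$counts, per_trajectory = summ$per_trajectory,
         outcomes = outcomes),
    file.path(out, "pathway_summary.json"), auto_unbox = FALSE, digits = NA
  )
  list(tag = tag, structure = structure, cmap = cmap, starts = starts,
       trajectories = trajs, series = series, labels = labels,
       outcomes = outcomes, fq = fq, hist2d = hist2d,
       contact_frequency = freq, summary = summ, seed = seed)
}

#' Run the full folding-study pipeline
#'
#' Prepares the system(s) (contact map, optional m2,2G modification),
#' generates unfolded ensembles, runs Q-terminated folding trajectories,
#' and writes all analyses (Q series, F(Q), Q_tsl x Q_dsl histogram,
#' contact-frequency maps, pathway fractions) plus a manifest under the
#' configured output directory. With a `modification` residue set, both
#' systems are run and the base center-of-mass shift and hydrogen-bond
#' comparison for the modified site are added.
#'
#' @param config a [go_run_config()].
#' @return invisibly, a list with one entry per system plus `comparison`
#'   (when both systems ran) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "go_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  structure <- config$structure

  # fail fast before any simulation
  systems <- list()
  if (!is.null(config$modification)) {
    mod_structure <- apply_m22g(structure, config$modification)
  }

  set.seed(config$master_seed)
  sys_seeds <- sample.int(.Machine$integer.max - 1L, 2)

  cmap <- build_native_contacts(structure, cutoff = config$params$cutoff)
  systems$unmodified <- .run_one_system("unmodified", structure, cmap,
                                        config, sys_seeds[1])
  comparison <- NULL
  if (!is.null(config$modification)) {
    cmap_mod <- build_native_contacts(mod_structure,
                                      cutoff = config$params$cutoff)
    systems$modified <- .run_one_system("modified", mod_structure, cmap_mod,
                                        config, sys_seeds[2])
    comparison <- .compare_systems(systems$modified, systems$unmodified,
                                   config)
    jsonlite::write_json(comparison,
                         file.path(config$out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    master_seed = config$master_seed,
    system_seeds = sys_seeds,
    modification = config$modification,
    n_trajectories = config$n_trajectories,
    t_unfold = config$t_unfold, t_fold = config$t_fold,
    max_steps = config$max_steps, q_stop = config$q_stop,
    dt = config$dt, friction = config$friction, stride = config$stride,
    record_stride = config$record_stride, n_bins = config$n_bins,
    unfold_method = config$unfold_method,
    n_equil_steps = config$n_equil_steps,
    parameters = unclass(config$params),
    parameter_hash = rlang::hash(config$params),
    domains = lapply(config$domains, as.integer)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(systems, list(comparison = comparison, manifest = manifest)))
}

.compare_systems <- function(mod, unmod, config) {
  focus <- config$modification
  # neighbour: the residue whose base sits closest to the modified base
  # in the native state (its vl partner in the bundled fixtures)
  s <- unmod$structure
  base_idx <- which(s$atoms$base_atom & s$atoms$residue_index != focus)
  fcom <- .base_com(s$xyz, s, focus)
  d <- sqrt(rowSums((s$xyz[base_idx, , drop = FALSE] -
                     matrix(fcom, length(base_idx), 3, byrow = TRUE))^2))
  neighbor <- s$atoms$residue_index[base_idx[which.min(d)]]

  gate_domains <- intersect(c("dsl", "asl"), names(config$domains))
  gate <- stats::setNames(rep(config$q_stop, length(gate_domains)),
                          gate_domains)
  delta <- tryCatch(
    base_com_delta(mod$trajectories, unmod$trajectories,
                   mod$structure, unmod$structure, mod$cmap, unmod$cmap,
                   config$domains, focus, neighbor,
                   gate = if (length(gate) > 0) gate else NULL,
                   lambda_formed = config$params$lambda_formed),
    error = function(e) list(error = conditionMessage(e))
  )
  nhb <- function(sys) {
    frames <- .gate_frames(sys$trajectories, sys$cmap, config$domains,
                           gate, config$params$lambda_formed)
    if (length(frames) == 0) return(NA_real_)
    mean(vapply(frames, hbond_count, 0L, structure = sys$structure,
                res_a = focus, res_b = neighbor))
  }
  list(focus_residue = focus, neighbor_residue = neighbor,
       gate = as.list(gate), delta_d = delta,
       nhb_modified = nhb(mod), nhb_unmodified = nhb(unmod))
}
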