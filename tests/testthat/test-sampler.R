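test_that("identical seeds give identical trajectories", {
  s <- make_hairpin(3, 3)$structure
  cm <- build_native_contacts(s)
  p <- fixture_go_parameters()
  st <- simulation_state(s$xyz, s, temperature = 300, seed = 5)
  t1 <- langevin_run(st, s, cm, p, n_steps = 1500, seed = 5)
  t2 <- langevin_run(st, s, cm, p, n_steps = 1500, seed = 5)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$q, t2$q)
  t3 <- langevin_run(st, s, cm, p, n_steps = 1500, seed = 6)
  expect_false(identical(t1$frames[[length(t1$frames)]],
                         t3$frames[[length(t3$frames)]]))
})

test_that("zero-temperature dynamics dissipates energy monotonically", {
  s <- make_hairpin(3, 3)$structure
  cm <- build_native_contacts(s)
  p <- fixture_go_parameters()
  set.seed(1)
  pos <- s$xyz + matrix(rnorm(length(s$xyz), 0, 0.1), ncol = 3)
  st <- simulation_state(pos, s,
                         velocities = matrix(0, nrow(pos), 3),
                         temperature = 0, seed = 1)
  tr <- langevin_run(st, s, cm, p, n_steps = 2000, temperature = 0,
                     record_stride = 40)
  e <- tr$epot + tr$ekin
  expect_true(all(diff(e) <= 1e-8))
})

test_that("an unstable timestep is rejected", {
  s <- make_hairpin(3, 3)$structure
  cm <- build_native_contacts(s)
  st <- simulation_state(s$xyz, s, temperature = 300, seed = 1)
  expect_error(langevin_run(st, s, cm, go_parameters(), n_steps = 10,
                            dt = 0.05), "unstable")
})

test_that("a one-step budget terminates with outcome max_steps", {
  s <- make_hairpin(3, 3)$structure
  cm <- build_native_contacts(s)
  pos <- randomize_unfolded(s, seed = 3, cmap = cm)
  st <- simulation_state(pos, s, temperature = 300, seed = 3)
  tr <- run_folding(st, s, cm, fixture_go_parameters(), max_steps = 1,
                    seed = 3)
  expect_equal(tr$outcome, "max_steps")
  expect_equal(tr$steps, 1)
})

test_that("folding runs refuse already-folded starting points", {
  s <- make_hairpin(3, 3)$structure
  cm <- build_native_contacts(s)
  st <- simulation_state(s$xyz, s, temperature = 300, seed = 1)
  expect_error(run_folding(st, s, cm, fixture_go_parameters(),
                           max_steps = 100),
               "Q < 0.2")
})

test_that("the unfolded ensemble has zero formed contacts and replays", {
  s <- make_hairpin(3, 3)$structure
  cm <- build_native_contacts(s)
  p <- fixture_go_parameters()
  ens <- generate_unfolded_ensemble(s, cm, p, n_configs = 3, seed = 9,
                                    n_equil_steps = 2000)
  expect_length(ens, 3)
  for (st in ens) {
    expect_equal(compute_q(st$positions, cm,
                           lambda_formed = p$lambda_formed), 0)
    tu <- attr(st, "unfold_temperature")
    expect_gte(tu, 550)
    expect_lte(tu, 700)
  }
  ens2 <- generate_unfolded_ensemble(s, cm, p, n_configs = 3, seed = 9,
                                     n_equil_steps = 2000)
  expect_identical(lapply(ens, `[[`, "positions"),
                   lapply(ens2, `[[`, "positions"))
  # distinct configurations across the ensemble
  d <- max(abs(ens[[1]]$positions - ens[[2]]$positions))
  expect_gt(d, 1)
})

test_that("kinetic temperature thermalizes to the target", {
  s <- make_hairpin(4, 4)$structure
  cm <- build_native_contacts(s)
  p <- fixture_go_parameters()
  st <- simulation_state(s$xyz, s, temperature = 353, seed = 17)
  tr <- langevin_run(st, s, cm, p, n_steps = 3e4, dt = 0.001,
                     record_stride = 100)
  kin <- tr$ekin[-(1:50)]
  t_kin <- mean(2 * kin / (3 * nrow(s$xyz) * kB))
  expect_equal(t_kin, 353, tolerance = 0.03)
})

test_that("trajectories export as multi-model PDB with metadata", {
  s <- make_hairpin(3, 3)$structure
  cm <- build_native_contacts(s)
  st <- simulation_state(s$xyz, s, temperature = 300, seed = 2)
  tr <- langevin_run(st, s, cm, fixture_go_parameters(), n_steps = 500,
                     record_stride = 100)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(tr, s, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), length(tr$frames))
  expect_equal(sum(grepl("^ENDMDL", lines)), length(tr$frames))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$seed, 2)
  expect_equal(length(meta$q), length(tr$q))
})
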