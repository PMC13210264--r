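test_that("hairpin fixtures have the advertised size and contacts", {
  h <- make_hairpin(6, 4)
  s <- h$structure
  expect_equal(nrow(s$residues), 16)
  expect_equal(nrow(s$atoms), 80) # 5 pseudo-heavy atoms per residue
  cm <- build_native_contacts(s)
  # cross-strand (pairing) contacts: strand1 1-6 vs strand2 11-16
  cross <- sum(cm$contacts$res_i <= 6 & cm$contacts$res_j >= 11)
  expect_gte(cross, 6)
  expect_equal(compute_q(s$xyz, cm), 1.0)
  # every bonded pair below 2 A, fixtures round-trip through PDB I/O
  d <- sqrt(rowSums((s$xyz[s$bonds[, 1], ] - s$xyz[s$bonds[, 2], ])^2))
  expect_true(all(d < 2))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_frame(s, s$xyz, path)
  s2 <- read_structure(path)
  expect_equal(nrow(build_native_contacts(s2)$contacts),
               nrow(cm$contacts))
})

test_that("the toy tRNA covers five domains with intra and inter contacts", {
  m <- make_mini_trna(4, 4)
  s <- m$structure
  expect_setequal(names(m$domains), c("aas", "asl", "dsl", "tsl", "vl"))
  cm <- build_native_contacts(s)
  ct <- cm$contacts
  for (nm in names(m$domains)) {
    dom <- m$domains[[nm]]
    expect_gte(sum(ct$res_i %in% dom & ct$res_j %in% dom), 1)
    expect_equal(compute_q(s$xyz, cm, domain = dom), 1.0)
  }
  # dsl packs against the variable loop (elbow-like tertiary contacts)
  inter <- sum((ct$res_i %in% m$domains$dsl & ct$res_j %in% m$domains$vl) |
               (ct$res_i %in% m$domains$vl & ct$res_j %in% m$domains$dsl))
  expect_gte(inter, 1)
  # the modifiable site is a guanosine base-paired to a vl residue
  expect_equal(s$residues$base[m$g_site], "G")
  expect_true(m$g_partner %in% m$domains$vl)
  expect_gte(hbond_count(s$xyz, s, m$g_site, m$g_partner), 1)
  # determinism
  m2 <- make_mini_trna(4, 4)
  expect_identical(m2$structure$xyz, s$xyz)
})

test_that("scripted trajectories recover every prescribed fold order", {
  m <- make_mini_trna(3, 3)
  cm <- build_native_contacts(m$structure)
  orders <- list(
    c("asl", "tsl", "dsl"), c("asl", "dsl", "tsl"),
    c("tsl", "asl", "dsl"), c("tsl", "dsl", "asl"),
    c("dsl", "asl", "tsl"), c("dsl", "tsl", "asl")
  )
  for (ord in orders) {
    tr <- make_scripted_trajectory(m, ord, c(30, 60, 90), n_frames = 110,
                                   seed = 7)
    qs <- q_series(tr, cm, m$domains)
    pw <- classify_pathway(qs)
    expect_equal(pw$label, paste(ord, collapse = "->"))
    # events land within two frames of the prescribed fold times
    expect_true(all(abs(pw$events$frame - c(30, 60, 90)) <= 2))
  }
})

test_that("scripted trajectories without jitter are piecewise monotone", {
  m <- make_mini_trna(3, 3)
  cm <- build_native_contacts(m$structure)
  tr <- make_scripted_trajectory(m, c("tsl", "dsl"), c(30, 60),
                                 n_frames = 80, seed = 1, jitter = 0)
  qs <- q_series(tr, cm, m$domains)
  expect_true(all(diff(qs$q_tsl) >= -1e-12))
  expect_true(all(diff(qs$q_dsl) >= -1e-12))
  # a four-domain order matching the full hierarchy
  tr2 <- make_scripted_trajectory(m, c("asl", "tsl", "dsl", "aas"),
                                  c(20, 40, 60, 80), n_frames = 100,
                                  seed = 2)
  pw <- classify_pathway(q_series(tr2, cm, m$domains))
  expect_equal(pw$label, "asl->tsl->dsl->aas")
  expect_error(
    make_scripted_trajectory(m, c("asl"), c(200), n_frames = 100),
    "frame budget"
  )
  expect_error(
    make_scripted_trajectory(m, c("asl", "tsl"), c(50, 40), n_frames = 100),
    "increasing"
  )
})

test_that("randomized unfolded states satisfy the folding preconditions", {
  for (fx in list(make_hairpin(4, 4), make_mini_trna(3, 3))) {
    s <- fx$structure
    cm <- build_native_contacts(s)
    p1 <- randomize_unfolded(s, seed = 1, cmap = cm)
    expect_equal(compute_q(p1, cm), 0)
    # bonded distances preserved (exactly, well within the 10% contract)
    d_nat <- sqrt(rowSums((s$xyz[s$bonds[, 1], ] -
                           s$xyz[s$bonds[, 2], ])^2))
    d_new <- sqrt(rowSums((p1[s$bonds[, 1], ] - p1[s$bonds[, 2], ])^2))
    expect_equal(d_new, d_nat, tolerance = 1e-9)
    # different seeds diverge
    p2 <- randomize_unfolded(s, seed = 2, cmap = cm)
    expect_gt(max(abs(p1 - p2)), 1)
    # no non-bonded pair (beyond 1-3) below 2 A
    n <- nrow(s$atoms)
    dmat <- as.matrix(dist(p1))
    ex <- build_exclusions(s)
    dmat[ex] <- Inf
    dmat[ex[, 2:1]] <- Inf
    diag(dmat) <- Inf
    expect_gte(min(dmat), 2.0)
  }
})
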