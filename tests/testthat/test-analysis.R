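test_that("Q counts formed contacts against the lambda threshold", {
  s <- make_hairpin(3, 3)$structure
  cm <- build_native_contacts(s)
  expect_equal(compute_q(s$xyz, cm), 1.0)
  expect_equal(compute_q(s$xyz * 10, cm), 0)
  # two-contact map with hand-set distances: thresholds 4.56 and 3.6
  cm2 <- cm
  cm2$contacts <- data.frame(i = c(1L, 1L), j = c(2L, 3L),
                             res_i = c(1L, 1L), res_j = c(2L, 2L),
                             sigma = c(3.8, 3.0))
  fr <- rbind(c(0, 0, 0), c(4.0, 0, 0), c(0, 5.0, 0))
  expect_equal(compute_q(fr, cm2, lambda_formed = 1.2), 0.5)
  expect_error(compute_q(s$xyz, cm, domain = 999L), "domain")
})

test_that("Q is monotone under uniform compression toward native", {
  s <- make_hairpin(4, 4)$structure
  cm <- build_native_contacts(s)
  set.seed(4)
  expanded <- randomize_unfolded(s, seed = 4, cmap = cm)
  ctr <- colMeans(s$xyz)
  qs <- vapply(seq(0, 1, by = 0.1), function(a) {
    fr <- (1 - a) * expanded + a * s$xyz
    compute_q(fr, cm)
  }, 0.0)
  expect_equal(qs[1], 0)
  expect_equal(qs[11], 1)
  expect_true(all(diff(qs) >= -1e-12))
})

test_that("F(Q) follows -kB T ln P with masked empty bins", {
  # counts 8, 4, 4 at 353 K: bin-to-bin difference kB * 353 * ln 2
  q <- c(rep(0.125, 8), rep(0.46, 4), rep(0.80, 4))
  fq <- free_energy_profile(q, temperature = 353, n_bins = 20)
  occ <- fq$occupancy[fq$occupancy > 0]
  expect_equal(occ, c(8, 4, 4))
  f <- fq$F[!is.na(fq$F)]
  expect_equal(f[1], 0)
  expect_equal(f[2] - f[1], kB * 353 * log(2), tolerance = 1e-9)
  expect_equal(f[2] - f[1], 0.4862, tolerance = 1e-4)
  # uniform occupancy gives identically zero F
  fu <- free_energy_profile(rep(seq(0.025, 0.975, by = 0.05), 3), 353)
  expect_equal(max(abs(fu$F), na.rm = TRUE), 0, tolerance = 1e-12)
  # duplication invariance and temperature equivariance
  f2 <- free_energy_profile(c(q, q), 353)
  expect_equal(f2$F, fq$F)
  f3 <- free_energy_profile(q, 706)
  expect_equal(f3$F, 2 * fq$F, tolerance = 1e-12)
  expect_error(free_energy_profile(numeric(0), 353), "empty")
  expect_error(free_energy_profile(c(0.5, 1.2), 353), "0, 1")
})

test_that("pathway classification follows first persistent crossings", {
  ser <- scripted_series(list(asl = 10, tsl = 20, dsl = 30, aas = 40))
  pw <- classify_pathway(ser)
  expect_equal(pw$label, "asl->tsl->dsl->aas")
  # a 2-frame spike does not count; the persistent crossing later does
  ser2 <- scripted_series(list(tsl = 15, dsl = 35))
  ser2$q_dsl[5:6] <- 0.95
  pw2 <- classify_pathway(ser2, persistence = 5)
  expect_equal(pw2$label, "tsl->dsl")
  expect_equal(pw2$events$frame[pw2$events$domain == "dsl"], 35)
  # only one domain folding
  ser3 <- scripted_series(list(tsl = 12, dsl = Inf))
  pw3 <- classify_pathway(ser3)
  expect_equal(pw3$label, "tsl")
  expect_equal(nrow(pw3$events), 1)
  # nothing folds
  ser4 <- scripted_series(list(tsl = Inf, dsl = Inf))
  expect_equal(classify_pathway(ser4)$label, "none")
  # simultaneous crossings are flagged as ties, broken by name
  ser5 <- scripted_series(list(dsl = 20, tsl = 20))
  pw5 <- classify_pathway(ser5)
  expect_true(pw5$tie)
  expect_equal(pw5$label, "dsl->tsl")
})

test_that("pathway fractions are percentages over observed labels", {
  pf <- pathway_fractions(c("A", "A", "B"))
  expect_equal(sum(pf$fractions), 100, tolerance = 1e-2)
  expect_equal(pf$fractions[pf$labels == "A"], 200 / 3, tolerance = 1e-6)
  expect_equal(pathway_fractions("only")$fractions, 100)
  labels <- c(rep("tsl-second", 31), rep("other", 29))
  pf2 <- pathway_fractions(labels)
  expect_equal(pf2$fractions[pf2$labels == "tsl-second"], 51.67,
               tolerance = 1e-2)
  expect_error(pathway_fractions(character(0)), "empty")
})

test_that("contact frequency maps count per-residue-pair formation", {
  s <- make_hairpin(3, 3)$structure
  cm <- build_native_contacts(s)
  native <- s$xyz
  extended <- s$xyz * 10
  m_native <- contact_frequency_map(list(native, native), cm)
  m_ext <- contact_frequency_map(list(extended, extended), cm)
  m_half <- contact_frequency_map(list(native, extended), cm)
  expect_true(isSymmetric(m_native))
  pairs <- unique(cm$contacts[, c("res_i", "res_j")])
  for (k in seq_len(nrow(pairs))) {
    expect_equal(m_native[pairs$res_i[k], pairs$res_j[k]], 1.0)
    expect_equal(m_half[pairs$res_i[k], pairs$res_j[k]], 0.5)
  }
  expect_equal(max(m_ext), 0)
})

test_that("base center-of-mass distances follow the sign convention", {
  s <- make_mini_trna(3, 3)$structure
  # synthetic one-frame ensembles with a known distance shift
  fr1 <- s$xyz
  tr1 <- structure(list(frames = list(fr1)), class = "go_trajectory")
  cm <- build_native_contacts(s)
  m <- make_mini_trna(3, 3)
  same <- base_com_delta(list(tr1), list(tr1), s, s, cm, cm, m$domains,
                         m$g_site, m$g_partner, gate = NULL)
  expect_equal(same$delta, 0)
  # move the partner base 0.4 A closer in the "modified" ensemble
  idx <- which(s$atoms$residue_index == m$g_partner & s$atoms$base_atom)
  gcom <- colMeans(fr1[which(s$atoms$residue_index == m$g_site &
                             s$atoms$base_atom), , drop = FALSE])
  fr2 <- fr1
  dirv <- gcom - fr1[idx[1], ]
  dirv <- dirv / sqrt(sum(dirv^2))
  fr2[idx, ] <- sweep(fr2[idx, , drop = FALSE], 2, 0.4 * dirv, "+")
  tr2 <- structure(list(frames = list(fr2)), class = "go_trajectory")
  shifted <- base_com_delta(list(tr2), list(tr1), s, s, cm, cm, m$domains,
                            m$g_site, m$g_partner, gate = NULL)
  expect_equal(shifted$delta, -0.4, tolerance = 1e-6)
  expect_error(
    base_com_delta(list(tr1), list(tr1), s, s, cm, cm, m$domains,
                   m$g_site, m$g_partner, gate = c(dsl = 2)),
    "gate"
  )
})

test_that("hydrogen bonds use the heavy-atom donor/acceptor criterion", {
  m <- make_mini_trna(3, 3)
  s <- m$structure
  # native: G-site N1/N2 donors within 3.5 A of the partner N1 acceptor
  expect_equal(hbond_count(s$xyz, s, m$g_site, m$g_partner), 2L)
  expect_equal(hbond_count(s$xyz, s, m$g_partner, m$g_site), 2L)
  # separating the residues removes every bond
  fr <- s$xyz
  idx <- which(s$atoms$residue_index == m$g_partner)
  fr[idx, ] <- fr[idx, ] + 50
  expect_equal(hbond_count(fr, s, m$g_site, m$g_partner), 0L)
  # the m2,2G base loses its N2 donor
  s2 <- apply_m22g(s, m$g_site)
  expect_equal(hbond_count(s2$xyz, s2, m$g_site, m$g_partner), 1L)
})

test_that("2-D Q histograms expose the sequential-folding corners", {
  # strictly sequential trajectories: tsl folds fully before dsl starts
  qx <- c(seq(0, 1, length.out = 50), rep(1, 50))
  qy <- c(rep(0, 50), seq(0, 1, length.out = 50))
  h <- q2d_histogram(c(qx, qy), c(qy, qx))
  mass <- corner_diagonal_mass(h)
  expect_gt(mass$corner_mass, mass$diagonal_mass)
  # concomitant folding populates the diagonal instead
  h2 <- q2d_histogram(qx, qx)
  mass2 <- corner_diagonal_mass(h2)
  expect_gt(mass2$diagonal_mass, mass2$corner_mass)
})
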