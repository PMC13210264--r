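test_that("the native pair well matches its closed form", {
  eps <- 0.14
  sigma <- 3.5
  expect_identical(native_pair_energy(sigma, sigma, eps), 0)
  # independent 1-D minimization of the functional form
  opt <- optimize(native_pair_energy, c(2, 10), sigma = sigma, eps = eps,
                  tol = 1e-10)
  expect_equal(opt$minimum / sigma, sqrt(6 / 5), tolerance = 1e-6)
  expect_equal(opt$objective, -0.2679184 * eps, tolerance = 1e-6)
  expect_equal(opt$objective, -0.0375086, tolerance = 1e-6)
  # decay at long range
  expect_lt(abs(native_pair_energy(100 * sigma, sigma, eps)), 1e-10)
  expect_error(native_pair_energy(0, sigma, eps), "positive")
})

test_that("the non-native repulsion is positive and monotone", {
  expect_equal(nonnative_pair_energy(2.5, 2.5, 0.01), 0.04)
  expect_equal(nonnative_pair_energy(5, 2.5, 0.01), 4 * 0.01 / 4096)
  r <- seq(1, 8, by = 0.25)
  v <- nonnative_pair_energy(r, 2.5, 0.01)
  expect_true(all(v > 0))
  expect_true(all(diff(v) < 0))
  expect_error(nonnative_pair_energy(-1, 2.5, 0.01), "positive")
})

test_that("bonded terms vanish at native and follow their closed forms", {
  s <- toy_structure()
  p <- go_parameters()
  be <- bonded_energy(s$xyz, s, p)
  expect_equal(be$total, 0, tolerance = 1e-10)
  # single stretched bond: k (dr)^2 = 100 * 0.01 = 1
  atoms <- data.frame(name = c("C4'", "N1"), element = c("C", "N"),
                      residue_index = 1L)
  s2 <- go_structure(atoms, rbind(c(0, 0, 0), c(1.5, 0, 0)), "A")
  pos <- s2$xyz
  pos[2, 1] <- 1.6
  be2 <- bonded_energy(pos, s2, p)
  expect_equal(be2$bond_term, 1.0, tolerance = 1e-9)
  # dihedral rotated by pi from native: k (1 - cos(pi)) = 2
  atoms4 <- data.frame(
    name = c("P", "O5'", "C4'", "N1"), element = c("P", "O", "C", "N"),
    residue_index = 1L
  )
  xyz4 <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.2, 0),
                c(3.6, 1.2, 0.8))
  s4 <- go_structure(atoms4, xyz4, "A")
  # rotate atom 4 by pi about the 2-3 bond axis
  axis <- (xyz4[3, ] - xyz4[2, ]) / sqrt(sum((xyz4[3, ] - xyz4[2, ])^2))
  v <- xyz4[4, ] - xyz4[3, ]
  v_rot <- 2 * sum(v * axis) * axis - v # rotation by pi about axis
  pos4 <- xyz4
  pos4[4, ] <- xyz4[3, ] + v_rot
  be4 <- bonded_energy(pos4, s4, p)
  expect_equal(be4$dihedral_term, 2 * p$k_dihedral, tolerance = 1e-6)
})

test_that("analytic forces equal central differences on random states", {
  m <- make_mini_trna(3, 3)
  s <- m$structure
  cm <- build_native_contacts(s)
  p <- fixture_go_parameters()
  set.seed(11)
  for (rep in 1:4) {
    pos <- s$xyz + matrix(rnorm(length(s$xyz), 0, 0.25), ncol = 3)
    E <- total_energy_forces(pos, s, cm, p)
    for (kk in 1:8) {
      i <- sample(nrow(pos), 1)
      k <- sample(3, 1)
      fn <- numeric_force(pos, s, cm, p, i, k)
      expect_equal(E$forces[i, k], fn,
                   tolerance = 1e-5 * max(1, abs(fn)))
    }
  }
})

test_that("energy decomposition sums to the total", {
  s <- make_hairpin(3, 3)$structure
  cm <- build_native_contacts(s)
  p <- go_parameters()
  set.seed(2)
  pos <- s$xyz + matrix(rnorm(length(s$xyz), 0, 0.2), ncol = 3)
  E <- total_energy_forces(pos, s, cm, p)
  parts <- E$native_term + E$nonnative_term + E$bond_term + E$angle_term +
    E$dihedral_term
  expect_equal(E$total, parts, tolerance = 1e-9 * max(1, abs(E$total)))
})

test_that("energy is invariant and forces sum to zero under rigid moves", {
  s <- make_hairpin(3, 3)$structure
  cm <- build_native_contacts(s)
  p <- go_parameters()
  set.seed(3)
  pos <- s$xyz + matrix(rnorm(length(s$xyz), 0, 0.15), ncol = 3)
  E0 <- total_energy_forces(pos, s, cm, p)
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  E1 <- total_energy_forces(sweep(pos %*% R, 2, c(5, -3, 2), "+"), s, cm, p)
  expect_equal(E1$total, E0$total, tolerance = 1e-9 * abs(E0$total))
  expect_equal(colSums(E0$forces), c(0, 0, 0), tolerance = 1e-9)
  # net torque about the origin
  tq <- colSums(cbind(
    pos[, 2] * E0$forces[, 3] - pos[, 3] * E0$forces[, 2],
    pos[, 3] * E0$forces[, 1] - pos[, 1] * E0$forces[, 3],
    pos[, 1] * E0$forces[, 2] - pos[, 2] * E0$forces[, 1]
  ))
  expect_equal(tq, c(0, 0, 0), tolerance = 1e-8)
})

test_that("at the native state the bonded forces vanish and a native pair
           pushes outward with 8 eps / sigma", {
  s <- make_hairpin(3, 3)$structure
  p <- go_parameters()
  be <- bonded_energy(s$xyz, s, p)
  expect_equal(be$total, 0, tolerance = 1e-9)
  # printed 12-10 form: at r = sigma the pair force magnitude is
  # 8 eps / sigma, directed to lengthen the pair
  eps <- 0.14
  sigma <- 3.5
  h <- 1e-7
  f <- -(native_pair_energy(sigma + h, sigma, eps) -
         native_pair_energy(sigma - h, sigma, eps)) / (2 * h)
  expect_equal(f, 8 * eps / sigma, tolerance = 1e-5)
  expect_equal(8 * 0.14 / 3.5, 0.32)
})

test_that("the standard structure-based form has its minimum at sigma", {
  p <- go_parameters(form = "standard")
  s <- make_hairpin(3, 3)$structure
  cm <- build_native_contacts(s)
  E <- total_energy_forces(s$xyz, s, cm, p)
  expect_equal(E$native_term, -p$eps_native * nrow(cm$contacts),
               tolerance = 1e-9)
})

test_that("overlapping non-native atoms raise a singularity error", {
  s <- toy_structure()
  cm <- build_native_contacts(s)
  pos <- s$xyz
  pos[6, ] <- pos[1, ] # P of residue 2 onto P of residue 1
  expect_error(total_energy_forces(pos, s, cm, go_parameters()),
               "overlapping")
})
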