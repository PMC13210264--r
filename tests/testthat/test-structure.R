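test_that("PDB round trip preserves atoms, residues and coordinates", {
  s <- toy_structure()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_frame(s, s$xyz, path)
  s2 <- read_structure(path)
  expect_equal(nrow(s2$atoms), 10)
  expect_equal(nrow(s2$residues), 2)
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$residue_index, s$atoms$residue_index)
  expect_equal(s2$residues$base, s$residues$base)
  expect_equal(s2$xyz, s$xyz, tolerance = 1e-3)
  # PDB fixed-width rounding to 0.001 A
  pos <- s$xyz
  pos[1, 1] <- 1.23456
  write_frame(s, pos, path)
  s3 <- read_structure(path)
  expect_equal(s3$xyz[1, 1], 1.235, tolerance = 1e-9)
})

test_that("hydrogens are dropped unless requested", {
  s <- toy_structure()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_frame(s, s$xyz, path)
  # append two hydrogens to residue 1 by editing the file
  lines <- readLines(path)
  atom_lines <- grep("^ATOM", lines)
  h1 <- lines[atom_lines[5]]
  substr(h1, 13, 16) <- " H1 "
  substr(h1, 77, 78) <- " H"
  lines <- append(lines, h1, after = atom_lines[5])
  writeLines(lines, path)
  expect_equal(nrow(read_structure(path)$atoms), 10)
  expect_equal(nrow(read_structure(path, include_hydrogens = TRUE)$atoms),
               11)
})

test_that("multi-chain and unknown-residue files are rejected", {
  s <- toy_structure()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_frame(s, s$xyz, path)
  lines <- readLines(path)
  idx <- grep("^ATOM", lines)
  # flip the second residue to chain B
  for (k in idx[6:10]) {
    substr(lines[k], 22, 22) <- "B"
  }
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path2)
  expect_error(read_structure(path2), "chains")

  lines <- readLines(path)
  for (k in idx[6:10]) {
    substr(lines[k], 18, 20) <- "XXX"
  }
  writeLines(lines, path2)
  expect_error(read_structure(path2), "XXX")
})

test_that("write_frame validates the position count", {
  s <- toy_structure()
  expect_error(write_frame(s, s$xyz[-1, ], tempfile()), "atoms")
})

test_that("m2,2G insertion adds exactly two methyl carbons at 1.45 A", {
  m <- make_mini_trna(3, 4)
  s <- m$structure
  n0 <- nrow(s$atoms)
  s2 <- apply_m22g(s, m$g_site)
  expect_equal(nrow(s2$atoms), n0 + 2)
  expect_equal(nrow(s2$bonds), nrow(s$bonds) + 2)
  expect_equal(s2$residues$base[m$g_site], "G2M")
  idx <- which(s2$atoms$residue_index == m$g_site)
  nm <- s2$atoms$name[idx]
  expect_true(all(c("CM1", "CM2") %in% nm))
  n2 <- s2$xyz[idx[match("N2", nm)], ]
  for (cmx in c("CM1", "CM2")) {
    d <- sqrt(sum((s2$xyz[idx[match(cmx, nm)], ] - n2)^2))
    expect_equal(d, 1.45, tolerance = 0.01)
  }
  # all pre-existing interatomic distances unchanged
  keep <- which(!(s2$atoms$name %in% c("CM1", "CM2")))
  old_d <- dist(s$xyz)
  new_d <- dist(s2$xyz[keep, ])
  expect_equal(as.vector(new_d), as.vector(old_d), tolerance = 1e-12)
})

test_that("m2,2G preconditions are enforced", {
  m <- make_mini_trna(3, 4)
  not_g <- setdiff(seq_len(nrow(m$structure$residues)), m$g_site)[1]
  expect_error(apply_m22g(m$structure, not_g), "not G")
  s <- toy_structure() # its G residue has no N2
  expect_error(apply_m22g(s, 2), "N2")
})

test_that("domain assignment parses ranges and enforces disjointness", {
  m <- make_mini_trna(3, 4)
  s <- m$structure
  d <- assign_domains(s, list(asl = "5-9", tsl = "12-15,17"))
  expect_equal(d$asl, 5:9)
  expect_equal(d$tsl, c(12:15, 17L))
  expect_error(assign_domains(s, list(a = "5-9", b = "8-12")), "overlap")
  expect_error(assign_domains(s, list(a = "1-1000")), "outside")
  expect_length(assign_domains(s, list()), 0)
  # config file round trip
  path <- withr::local_tempfile(fileext = ".cfg")
  write_domain_config(d, path)
  d2 <- assign_domains(s, read_domain_config(path))
  expect_equal(unclass(d2), unclass(d), ignore_attr = TRUE)
})

test_that("no residue is ever assigned to two domains", {
  m <- make_mini_trna(4, 4)
  doms <- m$domains
  all_res <- unlist(doms)
  expect_equal(anyDuplicated(all_res), 0)
})
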