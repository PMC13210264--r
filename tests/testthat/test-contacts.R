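test_that("bonded exclusions enumerate 1-2 and 1-3 pairs only", {
  # linear chain a-b-c: all three pairs excluded; a-d in a 4-chain kept
  atoms <- data.frame(
    name = c("P", "O5'", "C4'", "N1"), element = c("P", "O", "C", "N"),
    residue_index = 1L, stringsAsFactors = FALSE
  )
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0, 0), c(3.0, 1.47, 0))
  s <- go_structure(atoms, xyz, "A")
  ex <- build_exclusions(s)
  key <- paste(ex[, 1], ex[, 2])
  # chain P-O5'-C4'-N1: 1-2 pairs and 1-3 pairs present, 1-4 absent
  expect_true(all(c("1 2", "2 3", "3 4", "1 3", "2 4") %in% key))
  expect_false("1 4" %in% key)
})

test_that("contact extraction is exact on a hand-placed pseudo-atom case", {
  # four pseudo-atoms, two residues, no exclusions, intra-residue kept
  atoms <- data.frame(
    name = c("N1", "N3", "N1", "N3"), element = "N",
    residue_index = c(1L, 1L, 2L, 2L), stringsAsFactors = FALSE
  )
  xyz <- rbind(c(0, 0, 0), c(0, 0, 3.8), c(0, 0, 7.6), c(0, 3.0, 0))
  s <- structure(
    list(atoms = cbind(atoms, index = 1:4, mass = 14.007,
                       base_atom = TRUE),
         residues = data.frame(index = 1:2, base = "A"),
         xyz = xyz, bonds = matrix(integer(0), ncol = 2), chain_id = "A"),
    class = "go_structure"
  )
  cm <- build_native_contacts(s, cutoff = 4.0,
                              exclusions = matrix(integer(0), ncol = 2),
                              include_intra_residue = TRUE)
  expect_equal(cm$contacts[, c("i", "j")],
               data.frame(i = c(1L, 1L, 2L), j = c(2L, 4L, 3L)),
               ignore_attr = TRUE)
  expect_equal(sort(cm$contacts$sigma), c(3.0, 3.8, 3.8))
  # with bonds 1-2, 2-3 excluded and intra-residue filtering on
  s$bonds <- rbind(c(1L, 2L), c(2L, 3L))
  cm2 <- build_native_contacts(s, cutoff = 4.0,
                               exclusions = s$bonds,
                               include_intra_residue = FALSE,
                               min_bond_sep = 2)
  expect_equal(nrow(cm2$contacts), 1)
  expect_equal(cm2$contacts$i, 1L)
  expect_equal(cm2$contacts$j, 4L)
  expect_equal(cm2$contacts$sigma, 3.0)
  # a vanishing cutoff leaves no contacts
  expect_equal(nrow(build_native_contacts(s, cutoff = 0.1,
                                          exclusions = s$bonds)$contacts),
               0)
})

test_that("builder equals the brute-force all-pairs oracle", {
  set.seed(42)
  cases <- list(
    make_hairpin(3, 3), make_hairpin(5, 4), make_hairpin(6, 5),
    make_mini_trna(3, 3), make_mini_trna(4, 4)
  )
  for (fx in cases) {
    s <- fx$structure
    cm <- build_native_contacts(s)
    bf <- brute_force_contacts(s)
    got <- paste(cm$contacts$i, cm$contacts$j)
    want <- paste(bf[, 1], bf[, 2])
    expect_setequal(got, want)
    # sigma recomputes from native coordinates
    sig <- sqrt(rowSums((s$xyz[cm$contacts$i, , drop = FALSE] -
                         s$xyz[cm$contacts$j, , drop = FALSE])^2))
    expect_equal(cm$contacts$sigma, sig, tolerance = 1e-6)
  }
})

test_that("contact sets are monotone in the cutoff", {
  s <- make_hairpin(4, 4)$structure
  key <- function(cm) paste(cm$contacts$i, cm$contacts$j)
  c35 <- build_native_contacts(s, cutoff = 3.5)
  c40 <- build_native_contacts(s, cutoff = 4.0)
  c45 <- build_native_contacts(s, cutoff = 4.5)
  expect_true(all(key(c35) %in% key(c40)))
  expect_true(all(key(c40) %in% key(c45)))
})

test_that("contact map TSV round trips", {
  s <- make_hairpin(4, 4)$structure
  cm <- build_native_contacts(s)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contact_map(cm, path)
  cm2 <- read_contact_map(path, structure = s)
  expect_equal(cm2$contacts, cm$contacts, tolerance = 1e-12,
               ignore_attr = TRUE)
})
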