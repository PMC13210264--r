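# The Go potential: a 12-10 well for native contacts, 12th-power repulsion
# for everything else, plus harmonic/periodic bonded terms whose equilibria
# are measured from the native structure.

#' Go-model parameters
#'
#' Defaults follow common structure-based-model practice for RNA folding:
#' native/non-native well depths 0.14 and 0.01 kcal/mol, a 4 angstrom
#' native-contact cutoff, a single 2.5 angstrom repulsive radius for
#' non-native pairs, and native-geometry bonded terms.
#'
#' @param eps_native native-contact well depth (kcal/mol).
#' @param eps_nonnative non-native repulsion strength (kcal/mol).
#' @param cutoff native-contact cutoff (angstrom).
#' @param sigma_rep repulsive radius for non-native pairs (angstrom).
#' @param k_bond harmonic bond constant (kcal/mol/A^2), energy k (r - r0)^2.
#' @param k_angle harmonic angle constant (kcal/mol/rad^2).
#' @param k_dihedral dihedral constant (kcal/mol), energy k (1 - cos(phi - phi0)).
#' @param lambda_formed contact-formation multiplier: a native contact
#'   counts as formed when r < lambda * sigma.
#' @param form `"printed"` for 4 eps ((s/r)^12 - (s/r)^10) (zero at r = s,
#'   minimum at r = 1.0954 s), or `"standard"` for the conventional
#'   structure-based eps (5 (s/r)^12 - 6 (s/r)^10) with its minimum at s.
#' @return A `go_parameters` list.
#' @export
go_parameters <- function(eps_native = 0.14, eps_nonnative = 0.01,
                          cutoff = 4.0, sigma_rep = 2.5, k_bond = 100,
                          k_angle = 20, k_dihedral = 1,
                          lambda_formed = 1.2,
                          form = c("printed", "standard")) {
  form <- match.arg(form)
  stopifnot(eps_native > eps_nonnative, eps_nonnative > 0, sigma_rep > 0,
            lambda_formed >= 1, cutoff > 0)
  structure(
    list(eps_native = eps_native, eps_nonnative = eps_nonnative,
         cutoff = cutoff, sigma_rep = sigma_rep, k_bond = k_bond,
         k_angle = k_angle, k_dihedral = k_dihedral,
         lambda_formed = lambda_formed, form = form),
    class = "go_parameters"
  )
}

#' Native-contact pair energy
#'
#' `4 * eps * ((sigma/r)^12 - (sigma/r)^10)`: zero at `r = sigma`, minimum
#' `-0.26792 * eps` at `r = sigma * sqrt(6/5)`. Vectorized over `r`.
#'
#' @param r pair distance (angstrom), positive.
#' @param sigma native pair distance (angstrom).
#' @param eps well depth (kcal/mol).
#' @export
native_pair_energy <- function(r, sigma, eps) {
  if (any(r <= 0)) stop("pair distance must be positive")
  sr <- sigma / r
  4 * eps * (sr^12 - sr^10)
}

#' Non-native pair repulsion
#'
#' `4 * eps * (sigma_rep/r)^12`: strictly positive and monotonically
#' decreasing in `r`.
#'
#' @param r pair distance (angstrom), positive.
#' @param sigma_rep repulsive radius (angstrom).
#' @param eps repulsion strength (kcal/mol).
#' @export
nonnative_pair_energy <- function(r, sigma_rep, eps) {
  if (any(r <= 0)) stop("pair distance must be positive")
  4 * eps * (sigma_rep / r)^12
}

# Bonded topology + native equilibria: bonds from the bond graph, angles as
# all bonded triples, dihedrals as all simple bonded 4-paths.
.bonded_geometry <- function(structure) {
  xyz <- structure$xyz
  bonds <- structure$bonds
  n <- nrow(structure$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]
    j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  bond_r0 <- sqrt(rowSums((xyz[bonds[, 1], , drop = FALSE] -
                           xyz[bonds[, 2], , drop = FALSE])^2))
  ang <- list()
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) >= 2) {
      cmb <- t(utils::combn(nb, 2))
      ang[[length(ang) + 1]] <- cbind(cmb[, 1], j, cmb[, 2])
    }
  }
  ang <- if (length(ang) > 0) do.call(rbind, ang) else
    matrix(integer(0), ncol = 3)
  theta0 <- if (nrow(ang) > 0) {
    vapply(seq_len(nrow(ang)), function(k) {
      d <- xyz[ang[k, 1], ] - xyz[ang[k, 2], ]
      e <- xyz[ang[k, 3], ] - xyz[ang[k, 2], ]
      acos(max(-1, min(1, sum(d * e) / sqrt(sum(d^2) * sum(e^2)))))
    }, 0.0)
  } else numeric(0)
  dih <- list()
  for (k in seq_len(nrow(bonds))) {
    j <- bonds[k, 1]
    l <- bonds[k, 2]
    for (i in adj[[j]]) {
      if (i == l) next
      for (m in adj[[l]]) {
        if (m == j || m == i) next
        dih[[length(dih) + 1]] <- c(i, j, l, m)
      }
    }
  }
  dih <- if (length(dih) > 0) do.call(rbind, dih) else
    matrix(integer(0), ncol = 4)
  phi0 <- if (nrow(dih) > 0) {
    vapply(seq_len(nrow(dih)), function(k) {
      .dihedral_angle(xyz[dih[k, 1], ], xyz[dih[k, 2], ], xyz[dih[k, 3], ],
                      xyz[dih[k, 4], ])
    }, 0.0)
  } else numeric(0)
  ok <- is.finite(phi0)
  list(
    bonds = bonds, bond_r0 = bond_r0,
    angles = ang, theta0 = theta0,
    dihedrals = dih[ok, , drop = FALSE], phi0 = phi0[ok]
  )
}

.dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  c1 <- .cross3(b1, b2)
  c2 <- .cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (nb2 < 1e-12 || sum(c1^2) < 1e-16 || sum(c2^2) < 1e-16) return(NA_real_)
  atan2(sum(.cross3(c1, c2) * b2) / nb2, sum(c1 * c2))
}

# Assemble the 0-based arrays handed to the C++ kernels.
.cpp_system <- function(structure, cmap, params) {
  geom <- .bonded_geometry(structure)
  excl <- cmap$exclusions
  nat <- cmap$contacts
  skip_i <- c(excl[, 1], nat$i)
  skip_j <- c(excl[, 2], nat$j)
  # bonded-proximity pairs that sit inside the repulsive radius in the
  # native state are held there by the bonded terms; exposing them to the
  # excluded-volume repulsion would strain the native geometry, so they
  # are skipped.
  prox <- bonded_proximity_pairs(structure, 5L)
  if (nrow(prox) > 0) {
    dn <- sqrt(rowSums((structure$xyz[prox[, 1], , drop = FALSE] -
                        structure$xyz[prox[, 2], , drop = FALSE])^2))
    close_prox <- prox[dn < params$sigma_rep, , drop = FALSE]
    skip_i <- c(skip_i, close_prox[, 1])
    skip_j <- c(skip_j, close_prox[, 2])
  }
  # other intra-residue pairs are neither native contacts nor excluded
  # from repulsion beyond 1-3; they remain in the repulsive sum.
  list(
    bond_i = geom$bonds[, 1] - 1L, bond_j = geom$bonds[, 2] - 1L,
    bond_r0 = geom$bond_r0,
    angle_i = geom$angles[, 1] - 1L, angle_j = geom$angles[, 2] - 1L,
    angle_k = geom$angles[, 3] - 1L, angle_theta0 = geom$theta0,
    dih_i = geom$dihedrals[, 1] - 1L, dih_j = geom$dihedrals[, 2] - 1L,
    dih_k = geom$dihedrals[, 3] - 1L, dih_l = geom$dihedrals[, 4] - 1L,
    dih_phi0 = geom$phi0,
    nat_i = nat$i - 1L, nat_j = nat$j - 1L, nat_sigma = nat$sigma,
    skip_i = as.integer(skip_i) - 1L, skip_j = as.integer(skip_j) - 1L,
    eps_native = params$eps_native, eps_nonnative = params$eps_nonnative,
    sigma_rep = params$sigma_rep, k_bond = params$k_bond,
    k_angle = params$k_angle, k_dihedral = params$k_dihedral,
    form = if (params$form == "printed") 0L else 1L
  )
}

#' Bonded energy components
#'
#' Harmonic bonds `k (r - r0)^2`, harmonic angles `k (theta - theta0)^2`
#' and periodic dihedrals `k (1 - cos(phi - phi0))`, with all equilibria
#' measured from the native structure (so the native configuration has
#' zero bonded energy by construction).
#'
#' @param positions coordinate matrix, one row per atom.
#' @param structure a [go_structure()].
#' @param params a [go_parameters()].
#' @return list with `bond_term`, `angle_term`, `dihedral_term`, `total`.
#' @export
bonded_energy <- function(positions, structure, params = go_parameters()) {
  cmap0 <- structure(
    list(contacts = data.frame(i = integer(0), j = integer(0),
                               res_i = integer(0), res_j = integer(0),
                               sigma = numeric(0)),
         exclusions = matrix(integer(0), ncol = 2),
         cutoff = params$cutoff, n_atoms = nrow(structure$atoms)),
    class = "go_contact_map"
  )
  p0 <- params
  p0$sigma_rep <- 1e-6 # truncates the repulsion away: bonded terms only
  sys <- .cpp_system(structure, cmap0, p0)
  r <- cpp_energy_forces(as.matrix(positions), sys, FALSE)
  list(bond_term = r$bond_term, angle_term = r$angle_term,
       dihedral_term = r$dihedral_term,
       total = r$bond_term + r$angle_term + r$dihedral_term)
}

#' Total Go-model energy and analytic forces
#'
#' Native 12-10 term over the contact map, 12th-power repulsion over all
#' remaining non-excluded pairs, plus the bonded terms. Forces are the
#' exact negative analytic gradient.
#'
#' @param positions coordinate matrix, one row per atom.
#' @param structure a [go_structure()].
#' @param cmap a contact map built from the same structure.
#' @param params a [go_parameters()].
#' @return An `EnergyReport` list: `total`, `native_term`,
#'   `nonnative_term`, `bond_term`, `angle_term`, `dihedral_term`,
#'   `forces` (matrix, kcal/mol/angstrom).
#' @export
total_energy_forces <- function(positions, structure, cmap,
                                params = go_parameters()) {
  positions <- as.matrix(positions)
  if (nrow(positions) != nrow(structure$atoms)) {
    stop("positions length does not match atom count")
  }
  sys <- .cpp_system(structure, cmap, params)
  cpp_energy_forces(positions, sys, TRUE)
}
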