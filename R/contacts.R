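# Native contact map extraction: heavy-atom pairs within a distance cutoff
# in the folded reference structure, minus bonded-neighbour exclusions.

#' Enumerate 1-2 and 1-3 bonded exclusions
#'
#' Returns all atom pairs separated by one or two bonds in the bond graph.
#' 1-4 pairs are deliberately retained for the non-bonded terms (their
#' geometry is governed by the dihedral terms).
#'
#' @param structure a [go_structure()].
#' @return two-column integer matrix of atom index pairs (i < j).
#' @export
build_exclusions <- function(structure) {
  bonds <- structure$bonds
  n <- nrow(structure$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]
    j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  pairs <- list()
  # 1-2
  pairs[[1]] <- bonds
  # 1-3: for every atom, all pairs of its neighbours
  p13 <- list()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- t(utils::combn(sort(nb), 2))
      p13[[length(p13) + 1]] <- cmb
    }
  }
  if (length(p13) > 0) pairs[[2]] <- do.call(rbind, p13)
  out <- do.call(rbind, pairs)
  out <- t(apply(out, 1, sort))
  out <- unique(out)
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Build the native contact map
#'
#' Native contacts are all heavy-atom pairs whose distance in the native
#' structure is at most `cutoff` (default 4 angstrom), excluding bonded
#' 1-2/1-3 neighbours, (by default) pairs within the same residue, and
#' (by default) pairs fewer than `min_bond_sep` bonds apart along the
#' covalent graph. The bond-separation rule removes bonded-proximity
#' pairs -- consecutive-residue backbone atoms whose mutual distance is
#' pinned near its native value by the bond/angle/dihedral terms at any
#' temperature -- so that Q measures folding rather than covalent
#' geometry; base-stacking pairs (six bonds apart) and all longer-range
#' contacts are retained. Each contact stores its native distance sigma.
#'
#' @param structure a [go_structure()].
#' @param cutoff contact distance cutoff in angstrom.
#' @param exclusions pair matrix as from [build_exclusions()].
#' @param include_intra_residue count pairs within one residue as contacts
#'   (default `FALSE`: intra-residue pairs are structural, not folding,
#'   contacts).
#' @param min_bond_sep minimum number of covalent bonds separating a
#'   contact pair (default 6; use 2 to keep every non-1-2/1-3 pair).
#' @return A `go_contact_map`: list with `contacts` (data frame `i`, `j`,
#'   `res_i`, `res_j`, `sigma`, ordered by (i, j)), `exclusions`, `cutoff`
#'   and `n_atoms`.
#' @export
build_native_contacts <- function(structure, cutoff = 4.0,
                                  exclusions = build_exclusions(structure),
                                  include_intra_residue = FALSE,
                                  min_bond_sep = 6) {
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(structure$atoms)
  if (n < 2) stop("structure has fewer than 2 atoms")
  xyz <- structure$xyz
  d <- as.matrix(stats::dist(xyz))
  hit <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    i <- hit[, 1]
    j <- hit[, 2]
    keep <- rep(TRUE, length(i))
    if (!is.null(exclusions) && nrow(exclusions) > 0) {
      keys <- i * (n + 1) + j
      ex_keys <- exclusions[, 1] * (n + 1) + exclusions[, 2]
      keep <- keep & !(keys %in% ex_keys)
    }
    if (min_bond_sep > 2 && !is.null(structure$bonds)) {
      prox <- bonded_proximity_pairs(structure, min_bond_sep - 1)
      if (nrow(prox) > 0) {
        keys <- i * (n + 1) + j
        px_keys <- prox[, 1] * (n + 1) + prox[, 2]
        keep <- keep & !(keys %in% px_keys)
      }
    }
    res <- structure$atoms$residue_index
    if (!include_intra_residue) keep <- keep & res[i] != res[j]
    i <- i[keep]
    j <- j[keep]
    contacts <- data.frame(
      i = i, j = j, res_i = res[i], res_j = res[j],
      sigma = d[cbind(i, j)]
    )
    contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
    rownames(contacts) <- NULL
  } else {
    contacts <- data.frame(i = integer(0), j = integer(0),
                           res_i = integer(0), res_j = integer(0),
                           sigma = numeric(0))
  }
  structure(
    list(contacts = contacts, exclusions = exclusions, cutoff = cutoff,
         n_atoms = n),
    class = "go_contact_map"
  )
}

#' @export
print.go_contact_map <- function(x, ...) {
  cat("Native contact map: ", nrow(x$contacts), " contacts at cutoff ",
      x$cutoff, " A over ", x$n_atoms, " atoms (",
      nrow(x$exclusions), " excluded bonded pairs)\n", sep = "")
  invisible(x)
}

#' Atom pairs within a given number of covalent bonds
#'
#' Breadth-first enumeration over the bond graph; used for the contact
#' map's bonded-proximity rule.
#'
#' @param structure a [go_structure()].
#' @param max_bonds maximum bond-path length.
#' @return two-column integer matrix of atom index pairs (i < j).
#' @export
bonded_proximity_pairs <- function(structure, max_bonds) {
  bonds <- structure$bonds
  n <- nrow(structure$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]
    j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  out <- vector("list", n)
  for (a in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[a] <- 0L
    frontier <- a
    for (depth in seq_len(max_bonds)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[dist[nxt] < 0]
      if (length(nxt) == 0) break
      dist[nxt] <- depth
      frontier <- nxt
    }
    reach <- which(dist > 0 & seq_len(n) > a)
    if (length(reach) > 0) out[[a]] <- cbind(a, reach)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) matrix(integer(0), ncol = 2) else res
}

#' Write a contact map as TSV
#'
#' Columns: `i`, `j` (atom indices), `residue_i`, `residue_j`,
#' `sigma_A` (native distance, angstrom), with a header line.
#'
#' @param cmap a `go_contact_map`.
#' @param path output path.
#' @export
write_contact_map <- function(cmap, path) {
  df <- cmap$contacts
  out <- data.frame(i = df$i, j = df$j, residue_i = df$res_i,
                    residue_j = df$res_j, sigma_A = df$sigma)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a contact map TSV written by [write_contact_map()]
#'
#' @param path TSV path.
#' @param structure optional [go_structure()] used to restore the
#'   exclusion list and atom count.
#' @param cutoff contact cutoff recorded on the returned object.
#' @return A `go_contact_map`.
#' @export
read_contact_map <- function(path, structure = NULL, cutoff = 4.0) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  contacts <- data.frame(i = df$i, j = df$j, res_i = df$residue_i,
                         res_j = df$residue_j, sigma = df$sigma_A)
  structure(
    list(
      contacts = contacts,
      exclusions = if (!is.null(structure)) build_exclusions(structure)
                   else matrix(integer(0), ncol = 2),
      cutoff = cutoff,
      n_atoms = if (!is.null(structure)) nrow(structure$atoms)
                else max(contacts$j, 0)
    ),
    class = "go_contact_map"
  )
}
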