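#' @useDynLib gofold, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif setNames optimize spline approx
#' @importFrom utils write.table read.table head tail
"_PACKAGE"

# ---- constants -----------------------------------------------------------

#' Boltzmann constant in kcal/(mol K)
#' @export
kB <- 0.0019872041

.BASES <- c("A", "C", "G", "U", "G2M")
.BASE_ALIASES <- c(
  A = "A", C = "C", G = "G", U = "U", G2M = "G2M",
  RA = "A", RC = "C", RG = "G", RU = "U",
  ADE = "A", CYT = "C", GUA = "G", URA = "U"
)

.ELEMENT_MASS <- c(
  C = 12.011, N = 14.007, O = 15.999, P = 30.973762, H = 1.008, S = 32.06
)

# nucleobase heavy-atom names (used to flag base atoms and for base COM)
.BASE_ATOM_NAMES <- c(
  "N1", "C2", "N2", "N3", "C4", "N4", "O2", "C5", "C6", "N6", "O4", "O6",
  "N7", "C8", "N9", "CM1", "CM2"
)

# heavy-atom hydrogen-bond donor/acceptor lists per base. The m2,2G base
# loses the N2 donor because both amine hydrogens are replaced by methyls.
.HB_DONORS <- list(
  A = c("N6"), C = c("N4"), G = c("N1", "N2"), U = c("N3"), G2M = c("N1")
)
.HB_ACCEPTORS <- list(
  A = c("N1", "N3", "N7"), C = c("O2", "N3"), G = c("O6", "N3", "N7"),
  U = c("O2", "O4"), G2M = c("O6", "N3", "N7")
)

# intra-residue heavy-atom bond templates (atom-name adjacency)
.template_edges <- function(base) {
  backbone <- list(
    c("P", "OP1"), c("P", "OP2"), c("P", "OP3"), c("P", "O5'"),
    c("O5'", "C5'"), c("C5'", "C4'"), c("C4'", "C3'"), c("C3'", "O3'"),
    c("C4'", "O4'"), c("O4'", "C1'"), c("C1'", "C2'"), c("C2'", "C3'"),
    c("C2'", "O2'"),
    # reduced (pseudo-atom) backbone adjacency; template edges are
    # distance-filtered, so these never misfire on full-atom residues
    c("O5'", "C4'"), c("C4'", "O3'"), c("C4'", "N1"), c("C4'", "N9")
  )
  purine <- list(
    c("C1'", "N9"), c("N9", "C8"), c("C8", "N7"), c("N7", "C5"),
    c("C5", "C6"), c("C6", "N1"), c("N1", "C2"), c("C2", "N3"),
    c("N3", "C4"), c("C4", "C5"), c("C4", "N9")
  )
  pyrimidine <- list(
    c("C1'", "N1"), c("N1", "C2"), c("C2", "N3"), c("N3", "C4"),
    c("C4", "C5"), c("C5", "C6"), c("C6", "N1"), c("C2", "O2")
  )
  extra <- switch(base,
    A = list(c("C6", "N6")),
    G = list(c("C6", "O6"), c("C2", "N2")),
    G2M = list(c("C6", "O6"), c("C2", "N2"), c("N2", "CM1"), c("N2", "CM2")),
    C = list(c("C4", "N4")),
    U = list(c("C4", "O4"))
  )
  ring <- if (base %in% c("A", "G", "G2M")) purine else pyrimidine
  c(backbone, ring, extra)
}

.element_of <- function(name, elesy = NA) {
  if (!is.na(elesy) && nzchar(trimws(elesy))) {
    return(toupper(trimws(elesy)))
  }
  first <- sub("[0-9']*$", "", sub("^[0-9]*", "", name))
  toupper(substr(first, 1, 1))
}

# ---- NativeStructure -----------------------------------------------------

#' Construct a native RNA structure object
#'
#' The container used throughout the package: an ordered single-chain
#' heavy-atom model with residues, coordinates (angstrom) and a bond graph.
#' Bonds are inferred from per-base atom-name templates, a distance
#' fallback that connects any leftover intra-residue fragments, and
#' O3'(i)-P(i+1) backbone links.
#'
#' @param atoms data frame with columns `name`, `element`, `residue_index`
#'   and optionally `mass` (amu, filled from the element if missing).
#' @param xyz numeric matrix (one row per atom) of coordinates in angstrom.
#' @param bases character vector of residue base codes (A, C, G, U, G2M),
#'   one per residue.
#' @param chain_id single chain identifier.
#' @return An object of class `go_structure` with elements `atoms`
#'   (data frame incl. `index` and `base_atom`), `residues`, `xyz`,
#'   `bonds` (two-column matrix, i < j) and `chain_id`.
#' @export
go_structure <- function(atoms, xyz, bases, chain_id = "A") {
  stopifnot(is.data.frame(atoms), nrow(atoms) == nrow(xyz), ncol(xyz) == 3)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  n_res <- max(atoms$residue_index)
  if (length(bases) != n_res) {
    stop("need one base code per residue (", n_res, " residues, ",
         length(bases), " bases)")
  }
  bad <- setdiff(bases, .BASES)
  if (length(bad) > 0) stop("unknown residue base(s): ", paste(bad, collapse = ", "))
  atoms$index <- seq_len(nrow(atoms))
  if (is.null(atoms$mass)) {
    atoms$mass <- unname(.ELEMENT_MASS[atoms$element])
  }
  if (anyNA(atoms$mass)) {
    stop("unknown element(s): ",
         paste(unique(atoms$element[is.na(atoms$mass)]), collapse = ", "))
  }
  atoms$base_atom <- atoms$name %in% .BASE_ATOM_NAMES
  for (r in seq_len(n_res)) {
    if (!any(atoms$base_atom[atoms$residue_index == r])) {
      stop("residue ", r, " has no nucleobase atoms")
    }
  }
  s <- structure(
    list(
      atoms = atoms[, c("index", "name", "element", "mass", "residue_index",
                        "base_atom")],
      residues = data.frame(index = seq_len(n_res), base = bases,
                            stringsAsFactors = FALSE),
      xyz = unname(as.matrix(xyz)),
      bonds = NULL,
      chain_id = chain_id
    ),
    class = "go_structure"
  )
  s$bonds <- .infer_bonds(s)
  .validate_bonds(s)
  s
}

#' @export
print.go_structure <- function(x, ...) {
  cat("Native RNA structure: ", nrow(x$residues), " residues, ",
      nrow(x$atoms), " heavy atoms, ", nrow(x$bonds), " bonds (chain ",
      x$chain_id, ")\n", sep = "")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a [go_structure()].
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

.infer_bonds <- function(s) {
  bonds <- list()
  for (r in seq_len(nrow(s$residues))) {
    idx <- which(s$atoms$residue_index == r)
    names_r <- s$atoms$name[idx]
    edges <- .template_edges(s$residues$base[r])
    present <- matrix(integer(0), ncol = 2)
    for (e in edges) {
      a <- match(e[1], names_r)
      b <- match(e[2], names_r)
      if (!is.na(a) && !is.na(b) &&
          sqrt(sum((s$xyz[idx[a], ] - s$xyz[idx[b], ])^2)) < 2.0) {
        present <- rbind(present, c(idx[a], idx[b]))
      }
    }
    # connect leftover fragments by shortest native distance
    comp <- .components(length(idx), cbind(match(present[, 1], idx),
                                           match(present[, 2], idx)))
    while (length(unique(comp)) > 1) {
      best <- NULL
      bestd <- Inf
      cs <- unique(comp)
      in1 <- which(comp == cs[1])
      out1 <- which(comp != cs[1])
      for (a in in1) {
        d <- sqrt(rowSums((s$xyz[idx[out1], , drop = FALSE] -
                           matrix(s$xyz[idx[a], ], length(out1), 3,
                                  byrow = TRUE))^2))
        m <- which.min(d)
        if (d[m] < bestd) {
          bestd <- d[m]
          best <- c(a, out1[m])
        }
      }
      if (bestd >= 2.0) {
        stop("cannot connect atoms of residue ", r,
             ": nearest fragment distance ", round(bestd, 2), " A >= 2 A")
      }
      present <- rbind(present, idx[best])
      comp[comp == comp[best[2]]] <- comp[best[1]]
    }
    bonds[[r]] <- present
  }
  bonds <- do.call(rbind, bonds)
  # backbone O3'(i) - P(i+1)
  for (r in seq_len(nrow(s$residues) - 1)) {
    o3 <- which(s$atoms$residue_index == r & s$atoms$name == "O3'")
    p <- which(s$atoms$residue_index == r + 1 & s$atoms$name == "P")
    if (length(o3) == 0) stop("residue ", r, " is missing backbone atom O3'")
    if (length(p) == 0) stop("residue ", r + 1, " is missing backbone atom P")
    bonds <- rbind(bonds, c(o3, p))
  }
  bonds <- t(apply(bonds, 1, sort))
  bonds <- unique(bonds)
  bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
}

.components <- function(n, edges) {
  comp <- seq_len(n)
  if (nrow(edges) == 0) return(comp)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- comp[edges[k, 1]]
      b <- comp[edges[k, 2]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

.validate_bonds <- function(s) {
  d <- sqrt(rowSums((s$xyz[s$bonds[, 1], , drop = FALSE] -
                     s$xyz[s$bonds[, 2], , drop = FALSE])^2))
  if (any(d >= 2.0)) {
    k <- which.max(d)
    stop("bonded pair ", s$bonds[k, 1], "-", s$bonds[k, 2],
         " has native distance ", round(max(d), 2), " A (must be < 2 A)")
  }
  invisible(TRUE)
}

# ---- PDB I/O -------------------------------------------------------------

#' Read a single-chain RNA structure from a PDB file
#'
#' Parses ATOM records (via bio3d), drops hydrogens unless requested,
#' renumbers residues sequentially from 1 and infers the bond graph from
#' per-base templates plus backbone connectivity.
#'
#' @param pdb_path path to a PDB file with one RNA chain.
#' @param include_hydrogens keep hydrogen atoms (default `FALSE`; the
#'   contact definition and hydrogen-bond criterion are heavy-atom only).
#' @return A [go_structure()] object.
#' @export
read_structure <- function(pdb_path, include_hydrogens = FALSE) {
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", pdb_path)
  chains <- unique(at$chain)
  chains <- chains[!is.na(chains)]
  if (length(chains) > 1) {
    stop("structure has multiple chains: ", paste(chains, collapse = ", "))
  }
  elesy <- if ("elesy" %in% names(at)) at$elesy else rep(NA, nrow(at))
  element <- mapply(.element_of, at$elety, elesy)
  keep <- rep(TRUE, nrow(at))
  if (!include_hydrogens) keep <- element != "H"
  at <- at[keep, , drop = FALSE]
  element <- element[keep]
  resid <- toupper(trimws(at$resid))
  unknown <- setdiff(unique(resid), names(.BASE_ALIASES))
  if (length(unknown) > 0) {
    stop("unknown residue name(s): ", paste(unknown, collapse = ", "))
  }
  res_key <- paste(at$chain, at$resno, at$insert)
  res_fac <- factor(res_key, levels = unique(res_key))
  residue_index <- as.integer(res_fac)
  bases <- unname(.BASE_ALIASES[resid[!duplicated(residue_index)]])
  atoms <- data.frame(
    name = trimws(at$elety), element = element,
    residue_index = residue_index, stringsAsFactors = FALSE
  )
  xyz <- cbind(at$x, at$y, at$z)
  go_structure(atoms, xyz, bases,
               chain_id = if (length(chains) == 1) chains else "A")
}

#' Write one coordinate frame as a PDB file
#'
#' The structure supplies atom/residue naming; `positions` supplies the
#' coordinates. Round-tripping through [read_structure()] reproduces the
#' coordinates to PDB precision (0.001 angstrom).
#'
#' @param structure a [go_structure()].
#' @param positions numeric matrix of coordinates, one row per atom.
#' @param path output file path.
#' @export
write_frame <- function(structure, positions, path) {
  positions <- as.matrix(positions)
  if (nrow(positions) != nrow(structure$atoms)) {
    stop("positions has ", nrow(positions), " rows but structure has ",
         nrow(structure$atoms), " atoms")
  }
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(positions)),
    resno = structure$atoms$residue_index,
    resid = structure$residues$base[structure$atoms$residue_index],
    eleno = structure$atoms$index,
    elety = structure$atoms$name,
    chain = rep(structure$chain_id, nrow(structure$atoms)),
    elesy = structure$atoms$element,
    o = rep(1, nrow(structure$atoms)),
    b = rep(0, nrow(structure$atoms))
  )
  invisible(path)
}

# ---- m2,2G modification --------------------------------------------------

#' Insert the m2,2G (N2,N2-dimethylguanosine) modification
#'
#' Adds the two exocyclic methyl carbons (CM1, CM2) bonded to N2 of a
#' guanosine at 1.45 angstrom in idealized trigonal in-plane geometry and
#' relabels the base as G2M. All pre-existing atoms are untouched, so every
#' pre-existing interatomic distance is preserved.
#'
#' @param structure a [go_structure()].
#' @param residue_index 1-based index of a G residue carrying an N2 atom.
#' @return A new `go_structure` with two extra atoms and two extra bonds.
#' @export
apply_m22g <- function(structure, residue_index) {
  res <- structure$residues
  if (residue_index < 1 || residue_index > nrow(res)) {
    stop("residue index ", residue_index, " out of range")
  }
  if (res$base[residue_index] != "G") {
    stop("residue ", residue_index, " is ", res$base[residue_index],
         ", not G; m2,2G applies to guanosine only")
  }
  idx <- which(structure$atoms$residue_index == residue_index)
  nm <- structure$atoms$name[idx]
  need <- c("N2", "C2")
  if (!all(need %in% nm)) {
    stop("residue ", residue_index, " lacks atom(s): ",
         paste(setdiff(need, nm), collapse = ", "))
  }
  third <- intersect(c("N3", "N1"), nm)
  if (length(third) == 0) {
    stop("residue ", residue_index,
         " needs N1 or N3 to define the base plane")
  }
  p_n2 <- structure$xyz[idx[match("N2", nm)], ]
  p_c2 <- structure$xyz[idx[match("C2", nm)], ]
  p_3 <- structure$xyz[idx[match(third[1], nm)], ]
  e1 <- p_n2 - p_c2
  e1 <- e1 / sqrt(sum(e1^2))
  nrm <- .cross3(e1, p_3 - p_c2)
  nn <- sqrt(sum(nrm^2))
  if (nn < 1e-8) stop("degenerate base plane at residue ", residue_index)
  nrm <- nrm / nn
  e2 <- .cross3(nrm, e1)
  # trigonal: C2-N2-CMx angle of 120 degrees, in the base plane
  cm1 <- p_n2 + 1.45 * (cos(pi / 3) * e1 + sin(pi / 3) * e2)
  cm2 <- p_n2 + 1.45 * (cos(pi / 3) * e1 - sin(pi / 3) * e2)

  last <- max(idx)
  n_old <- nrow(structure$atoms)
  new_atoms <- data.frame(
    name = c("CM1", "CM2"), element = c("C", "C"),
    residue_index = residue_index, mass = .ELEMENT_MASS[["C"]],
    stringsAsFactors = FALSE
  )
  atoms <- structure$atoms[, c("name", "element", "mass", "residue_index")]
  ins <- function(df, rows) {
    rbind(df[seq_len(last), , drop = FALSE], rows,
          if (last < n_old) df[(last + 1):n_old, , drop = FALSE])
  }
  atoms2 <- ins(atoms, new_atoms[, c("name", "element", "mass",
                                     "residue_index")])
  xyz2 <- rbind(structure$xyz[seq_len(last), , drop = FALSE], cm1, cm2,
                if (last < n_old)
                  structure$xyz[(last + 1):n_old, , drop = FALSE])
  bases2 <- structure$residues$base
  bases2[residue_index] <- "G2M"
  go_structure(atoms2, xyz2, bases2, chain_id = structure$chain_id)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- domains -------------------------------------------------------------

#' Assign residues to named structural domains
#'
#' Domains follow tRNA convention: `aas` (acceptor stem), `asl` (anticodon
#' stem loop), `dsl` (D-stem loop), `tsl` (T-stem loop), `vl` (variable
#' loop). Residues named by no range remain unassigned.
#'
#' @param structure a [go_structure()].
#' @param domain_config named list mapping domain names to integer vectors
#'   or range strings like `"27-43"` / `"27-43,49-65"`, or the path of a
#'   config file with `name: start-end[,start-end]` lines.
#' @return A `go_domains` object: named list of integer residue-index sets.
#' @export
assign_domains <- function(structure, domain_config) {
  if (is.character(domain_config) && length(domain_config) == 1 &&
      file.exists(domain_config)) {
    domain_config <- read_domain_config(domain_config)
  }
  n_res <- nrow(structure$residues)
  out <- list()
  for (nm in names(domain_config)) {
    v <- domain_config[[nm]]
    if (is.character(v)) v <- .parse_ranges(v)
    v <- sort(unique(as.integer(v)))
    if (length(v) > 0 && (min(v) < 1 || max(v) > n_res)) {
      stop("domain ", nm, " references residues outside 1..", n_res)
    }
    out[[nm]] <- v
  }
  if (length(out) > 1) {
    nms <- names(out)
    for (a in seq_along(out)) {
      for (b in seq_along(out)) {
        if (b <= a) next
        ov <- intersect(out[[a]], out[[b]])
        if (length(ov) > 0) {
          stop("domains ", nms[a], " and ", nms[b], " overlap at residues ",
               paste(range(ov), collapse = "-"))
        }
      }
    }
  }
  structure(out, class = "go_domains")
}

.parse_ranges <- function(s) {
  parts <- trimws(unlist(strsplit(s, ",")))
  parts <- parts[nzchar(parts)]
  unlist(lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(trimws(unlist(strsplit(p, "-"))))
      seq(ab[1], ab[2])
    } else {
      as.integer(p)
    }
  }))
}

#' Read a domain definition config file
#'
#' Lines have the form `name: start-end[,start-end]`; blank lines and
#' lines starting with `#` are ignored.
#'
#' @param path config file path.
#' @return named list of range strings, suitable for [assign_domains()].
#' @export
read_domain_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("cannot parse domain config line: ", ln)
    out[[trimws(kv[1])]] <- trimws(kv[2])
  }
  out
}

#' Write a domain definition config file
#' @param domains named list of residue index vectors (e.g. a `go_domains`).
#' @param path output path.
#' @export
write_domain_config <- function(domains, path) {
  fmt <- vapply(domains, function(v) {
    v <- sort(unique(as.integer(v)))
    runs <- split(v, cumsum(c(1, diff(v) != 1)))
    paste(vapply(runs, function(r) {
      if (length(r) == 1) as.character(r) else paste0(r[1], "-", r[length(r)])
    }, ""), collapse = ",")
  }, "")
  writeLines(paste0(names(domains), ": ", fmt), path)
  invisible(path)
}
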