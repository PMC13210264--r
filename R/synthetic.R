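# Synthetic fixtures: idealized stem-loop RNAs built from 5 pseudo-heavy
# atoms per residue (P, O5', C4', O3' backbone + one base nitrogen).
# Geometry uses a 3.8 A stacking rise and 2.9 A base-pairing distance so
# the 4 A contact rule yields both stacking and pairing contacts, while
# the backbone carries enough atoms that every native contact can be
# geometrically broken (needed for zero-contact unfolded states).

# local residue template offsets in the (tangent, u, v) frame, where v is
# the base direction
.RES_T <- list(
  P = c(0.00, 0.00, 0.00),
  `O5'` = c(1.15, 1.51, -0.35),
  `C4'` = c(2.30, 0.00, -0.70),
  N1 = c(2.30, 0.00, 0.77)
)
.O3_FRACTION <- 3.25 / 3.8 # O3' rides toward the next anchor
.O3_LATERAL <- c(0.75, -0.20) # (u, v) offsets of O3'
.RISE <- 3.8
.LOOP_SPACING <- 3.7
.PAIR_HALF <- 2.22 # strand anchor half-separation; N1-N1 comes to 2.9 A

.unit <- function(v) v / sqrt(sum(v^2))

# compact planar guanine-like ring (C2, N2, N3 around the base N1) for the
# modifiable G site, in the residue's (t, u, v) frame; kept tight and
# tilted away from the backbone so it neither clashes with the next
# residue nor with its own O3'
.gsite_ring <- function(p, fr) {
  loc <- function(t, u, v) p + t * fr$t + u * fr$u + v * fr$v
  list(c2 = loc(1.85, 0, 1.62), n2 = loc(2.45, 0, 2.38),
       n3 = loc(1.05, 0, 1.90))
}

# point at distance r1 from c1 and r2 from c2, as close as possible to a
# hint point; falls back to the c1-c2 axis blend when the spheres do not
# intersect
.sphere_intersect <- function(c1, r1, c2, r2, hint) {
  d <- c2 - c1
  L <- sqrt(sum(d^2))
  e <- d / L
  if (L >= r1 + r2 || L <= abs(r1 - r2)) {
    return(c1 + r1 * e * sign(r1 + r2 - L))
  }
  a <- (L^2 + r1^2 - r2^2) / (2 * L)
  h <- sqrt(max(0, r1^2 - a^2))
  w <- (hint - c1) - sum((hint - c1) * e) * e
  nw <- sqrt(sum(w^2))
  if (nw < 1e-8) {
    w <- if (abs(e[1]) < 0.9) .cross3(e, c(1, 0, 0)) else .cross3(e, c(0, 1, 0))
    nw <- sqrt(sum(w^2))
  }
  c1 + a * e + (h / nw) * w
}

.orthonormal_frame <- function(t, v) {
  t <- .unit(t)
  v <- v - sum(v * t) * t
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8) {
    v <- if (abs(t[1]) < 0.9) .cross3(t, c(1, 0, 0)) else .cross3(t, c(0, 1, 0))
    nv <- sqrt(sum(v^2))
  }
  v <- v / nv
  list(t = t, u = .cross3(t, v), v = v)
}

# Place atoms for a chain of residues given per-residue anchors (P
# positions), tangents and base directions. `full_base` marks residues
# that carry a full guanine-like base (N1, C2, N2, N3) instead of the
# single base nitrogen.
.place_residues <- function(anchors, tangents, vdirs, bases,
                            full_base = rep(FALSE, nrow(anchors))) {
  n <- nrow(anchors)
  atoms <- list()
  xyz <- list()
  for (i in seq_len(n)) {
    fr <- .orthonormal_frame(tangents[i, ], vdirs[i, ])
    p <- anchors[i, ]
    loc <- function(off) p + off[1] * fr$t + off[2] * fr$u + off[3] * fr$v
    pos_p <- loc(.RES_T$P)
    pos_o5 <- loc(.RES_T$`O5'`)
    pos_c4 <- loc(.RES_T$`C4'`)
    # O3' sits 1.95 A from C4' and 1.90 A from the next residue's P
    # (sphere-sphere intersection, offset along the residue's u axis);
    # falls back to a proportional collinear split at very sharp turns.
    p_next <- if (i < n) anchors[i + 1, ] else p + .RISE * fr$t
    d_c4 <- 1.95
    d_p <- 1.90
    seg <- p_next - pos_c4
    L <- sqrt(sum(seg^2))
    e <- seg / L
    if (L >= d_c4 + d_p - 0.05 || L <= abs(d_c4 - d_p) + 0.05) {
      sc <- L / (d_c4 + d_p)
      pos_o3 <- pos_c4 + (d_c4 * sc) * e
    } else {
      a_off <- (L^2 + d_c4^2 - d_p^2) / (2 * L)
      h <- sqrt(max(0, d_c4^2 - a_off^2))
      w <- fr$u - sum(fr$u * e) * e
      nw <- sqrt(sum(w^2))
      if (nw < 1e-6) {
        w <- fr$v - sum(fr$v * e) * e
        nw <- sqrt(sum(w^2))
      }
      pos_o3 <- pos_c4 + a_off * e + (h / nw) * w
    }
    pos_n1 <- loc(.RES_T$N1)
    names_i <- c("P", "O5'", "C4'", "O3'", "N1")
    pos_i <- rbind(pos_p, pos_o5, pos_c4, pos_o3, pos_n1)
    if (full_base[i]) {
      ring <- .gsite_ring(p, fr)
      names_i <- c(names_i, "C2", "N2", "N3")
      pos_i <- rbind(pos_i, ring$c2, ring$n2, ring$n3)
    }
    atoms[[i]] <- data.frame(
      name = names_i,
      element = substr(sub("[0-9']*$", "", names_i), 1, 1),
      residue_index = i, stringsAsFactors = FALSE
    )
    xyz[[i]] <- pos_i
  }
  list(atoms = do.call(rbind, atoms), xyz = do.call(rbind, xyz))
}

# Stem-loop anchors in local coordinates: strand up (+z) at y = +PAIR_HALF,
# an omega-shaped loop arc in the y-z plane, strand down at y = -PAIR_HALF.
.stem_loop_anchors <- function(n_bp, loop_len) {
  z1 <- .RISE * (seq_len(n_bp) - 1)
  s1 <- cbind(0, .PAIR_HALF, z1)
  t1 <- matrix(rep(c(0, 0, 1), n_bp), ncol = 3, byrow = TRUE)
  v1 <- matrix(rep(c(0, -1, 0), n_bp), ncol = 3, byrow = TRUE)
  # strand 2 carries a +4.6 z offset so the base nitrogens align in z
  z2 <- .RISE * (n_bp - seq_len(n_bp)) + 4.6
  s2 <- cbind(0, -.PAIR_HALF, z2)
  t2 <- matrix(rep(c(0, 0, -1), n_bp), ncol = 3, byrow = TRUE)
  v2 <- matrix(rep(c(0, 1, 0), n_bp), ncol = 3, byrow = TRUE)

  a <- s1[n_bp, ]
  b <- s2[1, ]
  chord <- sqrt(sum((b - a)^2))
  target <- .LOOP_SPACING * (loop_len + 1)
  if (target <= pi * chord / 2) {
    stop("loop_len too small to close the stem")
  }
  len_fun <- function(r) r * (2 * pi - 2 * asin(chord / (2 * r))) - target
  r <- stats::uniroot(len_fun, c(chord / 2 + 1e-6, 10 * target))$root
  mid <- (a + b) / 2
  cd <- .unit(b - a)
  # the loop arc stays in the pairing plane and bulges above the stem top
  ex <- .unit(c(0, cd[3], -cd[2]))
  if (ex[3] < 0) ex <- -ex
  m_off <- sqrt(r^2 - (chord / 2)^2)
  ctr <- mid + m_off * ex
  # circle in the (ex, cd) plane: p(phi) = ctr + r (cos(phi) ex + sin(phi) cd)
  phi_a <- atan2(sum((a - ctr) * cd), sum((a - ctr) * ex))
  phi_b <- atan2(sum((b - ctr) * cd), sum((b - ctr) * ex))
  dphi <- (phi_b - phi_a) %% (2 * pi)
  if (dphi < pi) dphi <- dphi - 2 * pi # the long arc spans > pi
  phis <- phi_a + dphi * seq_len(loop_len) / (loop_len + 1)
  lp <- t(vapply(phis, function(ph) ctr + r * (cos(ph) * ex + sin(ph) * cd),
                 numeric(3)))
  sgn <- sign(dphi)
  lt <- t(vapply(phis, function(ph) {
    sgn * (-sin(ph) * ex + cos(ph) * cd)
  }, numeric(3)))
  lv <- t(vapply(phis, function(ph) cos(ph) * ex + sin(ph) * cd,
                 numeric(3))) # outward radial
  list(
    anchors = rbind(s1, lp, s2),
    tangents = rbind(t1, lt, t2),
    vdirs = rbind(v1, lv, v2),
    stem1 = seq_len(n_bp),
    loop = n_bp + seq_len(loop_len),
    stem2 = n_bp + loop_len + seq_len(n_bp)
  )
}

#' Build an idealized RNA hairpin fixture
#'
#' A double-helical stem of `n_bp` base pairs closed by a loop, as a
#' 5-pseudo-atom-per-residue structure whose native contact map contains
#' at least `n_bp` cross-strand (pairing) contacts plus stacking contacts.
#'
#' @param n_bp number of base pairs (>= 3).
#' @param loop_len number of loop residues (>= 3).
#' @param seed recorded with the fixture (the geometry is deterministic).
#' @return list with `structure` (a [go_structure()]) and `domains`
#'   (single domain `stem` covering all residues).
#' @export
make_hairpin <- function(n_bp, loop_len, seed = 1L) {
  stopifnot(n_bp >= 3, loop_len >= 3)
  g <- .stem_loop_anchors(n_bp, loop_len)
  n <- nrow(g$anchors)
  bases <- rep(c("G", "C", "A", "U"), length.out = n)
  pl <- .place_residues(g$anchors, g$tangents, g$vdirs, bases)
  s <- go_structure(pl$atoms, pl$xyz, bases)
  attr(s, "seed") <- as.integer(seed)
  domains <- assign_domains(s, list(stem = seq_len(n)))
  list(structure = s, domains = domains)
}

#' Build a toy tRNA-like fixture with five structural domains
#'
#' Four stem-loop arms (`dsl`, `asl`, `tsl`, `aas`) radiate from a hub in
#' chain order dsl - asl - tsl - aas; the variable-loop linker (`vl`)
#' between asl and tsl is routed past the dsl arm and past the modifiable
#' G site so that inter-domain native contacts (dsl-vl) and a G-site/vl
#' base pair exist, echoing a tRNA elbow at toy scale. The first residue
#' of the dsl-asl junction carries a full guanine-like base (N1, C2, N2,
#' N3) so [apply_m22g()] can act on it; its index is returned as `g_site`
#' and its spatial base-pairing partner in the vl as `g_partner`.
#'
#' @param stem_bp base pairs per arm stem (>= 3).
#' @param loop_len loop residues per arm.
#' @param seed recorded with the fixture (geometry is deterministic).
#' @return list with `structure`, `domains` (all five domain names),
#'   `g_site`, `g_partner`.
#' @export
make_mini_trna <- function(stem_bp = 4, loop_len = 4, seed = 1L) {
  stopifnot(stem_bp >= 3)
  r0 <- 8.0
  arm_angles <- c(dsl = pi / 2, asl = pi, tsl = 0, aas = 3 * pi / 2)
  arm_local <- .stem_loop_anchors(stem_bp, loop_len)

  to_global <- function(theta, m) {
    u <- c(cos(theta), sin(theta), 0)
    w <- .cross3(c(0, 0, 1), u)
    t(apply(m, 1, function(p) p[1] * w + p[2] * c(0, 0, 1) + p[3] * u))
  }
  arm <- function(theta) {
    list(anchors = sweep(to_global(theta, arm_local$anchors), 2,
                         r0 * c(cos(theta), sin(theta), 0), "+"),
         tangents = to_global(theta, arm_local$tangents),
         vdirs = to_global(theta, arm_local$vdirs))
  }
  arms <- lapply(arm_angles, arm)

  n_arm <- nrow(arm_local$anchors)
  exit_of <- function(a) list(p = a$anchors[n_arm, ],
                              t = a$tangents[n_arm, ])
  entry_of <- function(a) list(p = a$anchors[1, ], t = a$tangents[1, ])

  bridge <- function(from, to, waypoints = NULL, spacing = .LOOP_SPACING) {
    ctrl <- rbind(from$p, from$p + 2.5 * from$t, waypoints,
                  to$p - 2.5 * to$t, to$p)
    cum <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
    tt <- seq(0, max(cum), length.out = 60 * nrow(ctrl))
    fine <- cbind(stats::spline(cum, ctrl[, 1], xout = tt)$y,
                  stats::spline(cum, ctrl[, 2], xout = tt)$y,
                  stats::spline(cum, ctrl[, 3], xout = tt)$y)
    arc <- c(0, cumsum(sqrt(rowSums(diff(fine)^2))))
    total <- max(arc)
    n_res <- max(1L, round(total / spacing) - 1L)
    at <- total * seq_len(n_res) / (n_res + 1)
    idx <- vapply(at, function(x) which.min(abs(arc - x)), 0L)
    anchors <- fine[idx, , drop = FALSE]
    # chord-based tangents over the realized anchor chain (robust to
    # spline overshoot near sharp waypoint turns)
    path <- rbind(from$p, anchors, to$p)
    tangents <- t(vapply(seq_len(n_res) + 1, function(k) {
      .unit(path[k + 1, ] - path[k - 1, ])
    }, numeric(3)))
    # bases point away from the hub axis
    vdirs <- t(apply(anchors, 1, function(p) {
      r <- c(p[1], p[2], 0)
      if (sqrt(sum(r^2)) < 1) r <- c(p[1], p[2], p[3])
      .unit(r)
    }))
    list(anchors = anchors, tangents = tangents, vdirs = vdirs)
  }

  j1 <- bridge(exit_of(arms$dsl), entry_of(arms$asl))
  # predicted G-site N2 position (first j1 residue, full base) to route
  # the vl past it
  fr <- .orthonormal_frame(j1$tangents[1, ], j1$vdirs[1, ])
  n2 <- .gsite_ring(j1$anchors[1, ], fr)$n2
  mid_path <- (exit_of(arms$asl)$p + entry_of(arms$tsl)$p) / 2
  w_g <- n2 + 3.2 * .unit(mid_path - n2)
  vl <- bridge(exit_of(arms$asl), entry_of(arms$tsl), waypoints = w_g)
  j2 <- bridge(exit_of(arms$tsl), entry_of(arms$aas))

  segs <- list(arms$dsl, j1, arms$asl, vl, arms$tsl, j2, arms$aas)
  anchors <- do.call(rbind, lapply(segs, `[[`, "anchors"))
  tangents <- do.call(rbind, lapply(segs, `[[`, "tangents"))
  vdirs <- do.call(rbind, lapply(segs, `[[`, "vdirs"))
  n <- nrow(anchors)
  lens <- vapply(segs, function(s) nrow(s$anchors), 0L)
  offs <- cumsum(c(0, lens))
  seg_idx <- lapply(seq_along(segs), function(k) offs[k] + seq_len(lens[k]))

  g_site <- seg_idx[[2]][1]
  # adenine-like residues throughout (their N1 is a hydrogen-bond
  # acceptor), guanine-like base at the modifiable site
  bases <- rep("A", n)
  bases[g_site] <- "G"
  full_base <- seq_len(n) == g_site
  pl <- .place_residues(anchors, tangents, vdirs, bases, full_base)
  # idealize the G-site base pair: the nearest vl base nitrogen is set
  # exactly 2.9 A from the G-site N2 (keeping its own C4'-N1 bond length)
  i_n2 <- which(pl$atoms$residue_index == g_site & pl$atoms$name == "N2")
  vl_res <- seg_idx[[4]]
  i_vln1 <- which(pl$atoms$residue_index %in% vl_res & pl$atoms$name == "N1")
  dn <- sqrt(rowSums((pl$xyz[i_vln1, , drop = FALSE] -
                      matrix(pl$xyz[i_n2, ], length(i_vln1), 3,
                             byrow = TRUE))^2))
  i_p <- i_vln1[which.min(dn)]
  res_p <- pl$atoms$residue_index[i_p]
  i_c4 <- which(pl$atoms$residue_index == res_p & pl$atoms$name == "C4'")
  pl$xyz[i_p, ] <- .sphere_intersect(pl$xyz[i_c4, ], 1.47,
                                     pl$xyz[i_n2, ], 2.9, pl$xyz[i_p, ])
  # any other vl base nitrogen crowding the site is re-aimed: scan
  # directions on its sugar bond sphere and keep the one with the best
  # clearance from all other atoms (and >= 2.9 A from the G-site N2)
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(dirs^2) > 0, ]
  dirs <- t(apply(dirs, 1, .unit))
  for (i_o in setdiff(i_vln1, i_p)) {
    if (sqrt(sum((pl$xyz[i_o, ] - pl$xyz[i_n2, ])^2)) < 2.9) {
      i_c4o <- which(pl$atoms$residue_index == pl$atoms$residue_index[i_o] &
                     pl$atoms$name == "C4'")
      others <- pl$xyz[-c(i_o, i_c4o), , drop = FALSE]
      best <- NULL
      best_clear <- -Inf
      for (k in seq_len(nrow(dirs))) {
        cand <- pl$xyz[i_c4o, ] + 1.47 * dirs[k, ]
        if (sqrt(sum((cand - pl$xyz[i_n2, ])^2)) < 2.9) next
        clear <- min(sqrt(rowSums((others -
          matrix(cand, nrow(others), 3, byrow = TRUE))^2)))
        if (clear > best_clear) {
          best_clear <- clear
          best <- cand
        }
      }
      pl$xyz[i_o, ] <- best
    }
  }
  s <- go_structure(pl$atoms, pl$xyz, bases)
  attr(s, "seed") <- as.integer(seed)

  domains <- assign_domains(s, list(
    dsl = c(seg_idx[[1]], seg_idx[[2]]), asl = seg_idx[[3]], vl = seg_idx[[4]],
    tsl = seg_idx[[5]], aas = seg_idx[[7]]
  ))
  list(structure = s, domains = domains, g_site = g_site,
       g_partner = res_p)
}

#' Build a scripted trajectory with a prescribed domain folding order
#'
#' Frames interpolate each domain from an expanded geometry (2.5x about
#' the global centroid, so no native contacts are formed) to native over a
#' short ramp ending at its fold time; a domain's intra-domain Q therefore
#' crosses 0.8 persistently within two frames of its fold time and not
#' before. Domains not named in `fold_order` (and unassigned residues)
#' stay expanded throughout.
#'
#' @param fixture output of [make_mini_trna()] (or any list with
#'   `structure` and `domains`).
#' @param fold_order character vector of domain names in folding order.
#' @param fold_times strictly increasing frame indices (each > 10 and
#'   <= `n_frames` - 5 so the persistence window fits).
#' @param n_frames total frames.
#' @param seed jitter seed.
#' @param jitter per-coordinate Gaussian jitter amplitude (angstrom).
#' @return a `go_trajectory` (frames, times, q).
#' @export
make_scripted_trajectory <- function(fixture, fold_order, fold_times,
                                     n_frames, seed = 1L, jitter = 0.02) {
  stopifnot(length(fold_order) == length(fold_times))
  if (any(diff(fold_times) <= 0)) stop("fold_times must be strictly increasing")
  if (max(fold_times) > n_frames - 5) {
    stop("fold_times exceed the frame budget (need 5 frames of headroom ",
         "within n_frames = ", n_frames, ")")
  }
  structure_ <- fixture$structure
  domains <- fixture$domains
  unknown <- setdiff(fold_order, names(domains))
  if (length(unknown) > 0) stop("unknown domain(s): ",
                                paste(unknown, collapse = ", "))
  xyz <- structure_$xyz
  ctr <- colMeans(xyz)
  res_of <- structure_$atoms$residue_index
  group_time <- rep(Inf, nrow(xyz))
  for (k in seq_along(fold_order)) {
    resids <- domains[[fold_order[k]]]
    group_time[res_of %in% resids] <- fold_times[k]
  }
  set.seed(seed)
  frames <- vector("list", n_frames)
  scale_at <- function(t, f) {
    if (!is.finite(f)) return(2.5)
    w <- min(10, f - 1)
    if (t <= f - w) 2.5 else if (t >= f) 1.0 else 2.5 - 1.5 * (t - (f - w)) / w
  }
  for (t in seq_len(n_frames)) {
    s <- vapply(group_time, scale_at, 0.0, t = t)
    fr <- sweep(sweep(xyz, 2, ctr) * s, 2, ctr, "+")
    if (jitter > 0) {
      fr <- fr + matrix(stats::rnorm(length(fr), 0, jitter), ncol = 3)
    }
    frames[[t]] <- fr
  }
  structure(
    list(frames = frames, times = as.numeric(seq_len(n_frames)),
         q = NULL, outcome = "scripted", steps = n_frames,
         metadata = list(seed = as.integer(seed), fold_order = fold_order,
                         fold_times = fold_times, jitter = jitter)),
    class = "go_trajectory"
  )
}

#' Generate a self-avoiding expanded (unfolded) configuration
#'
#' Rebuilds the chain atom by atom with native bond lengths but random,
#' outward-biased directions, rejecting placements that bring any
#' non-bonded pair below 2 angstrom or form any native contact. The
#' result has Q = 0 under the formation criterion while every bonded
#' distance equals its native value.
#'
#' @param structure a [go_structure()].
#' @param seed RNG seed.
#' @param cmap contact map (built from the structure when `NULL`).
#' @param lambda_formed formation multiplier used for the native-contact
#'   avoidance margin.
#' @param max_restarts whole-chain restart budget.
#' @return coordinate matrix with `compute_q(...) == 0`.
#' @export
randomize_unfolded <- function(structure, seed = 1L, cmap = NULL,
                               lambda_formed = 1.2, max_restarts = 40L) {
  if (is.null(cmap)) cmap <- build_native_contacts(structure)
  n <- nrow(structure$atoms)
  xyz_nat <- structure$xyz
  bonds <- structure$bonds
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]
    j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  # build order: breadth-first over the bond graph from atom 1 (bond
  # graph of a single chain is connected)
  parent <- rep(NA_integer_, n)
  order_ <- integer(0)
  visited <- rep(FALSE, n)
  queue <- 1L
  visited[1] <- TRUE
  while (length(queue) > 0) {
    a <- queue[1]
    queue <- queue[-1]
    order_ <- c(order_, a)
    for (b in adj[[a]]) {
      if (!visited[b]) {
        visited[b] <- TRUE
        parent[b] <- a
        queue <- c(queue, b)
      }
    }
  }
  # per-atom native contact partners and avoidance radii
  ct <- cmap$contacts
  partners <- vector("list", n)
  for (k in seq_len(nrow(ct))) {
    i <- ct$i[k]
    j <- ct$j[k]
    rad <- 1.22 * ct$sigma[k]
    partners[[i]] <- rbind(partners[[i]], c(j, rad))
    partners[[j]] <- rbind(partners[[j]], c(i, rad))
  }
  # 1-2 and 1-3 neighbours are exempt from the 2 A packing rule (their
  # separations are fixed by the bond geometry, and in the compact base
  # ring they sit below 2 A even in the native state)
  excl13 <- lapply(seq_len(n), function(a) {
    unique(c(a, adj[[a]], unlist(adj[adj[[a]]])))
  })
  bonded_to <- function(a) excl13[[a]]

  set.seed(seed)
  for (restart in seq_len(max_restarts)) {
    pos <- matrix(NA_real_, n, 3)
    pos[order_[1], ] <- c(0, 0, 0)
    ok_all <- TRUE
    backtracks <- 0L
    oi <- 2L
    while (oi <= length(order_)) {
      a <- order_[oi]
      pa <- parent[a]
      blen <- sqrt(sum((xyz_nat[a, ] - xyz_nat[pa, ])^2))
      placed <- order_[seq_len(oi - 1)]
      ctr <- colMeans(pos[placed, , drop = FALSE])
      outward <- pos[pa, ] - ctr
      no <- sqrt(sum(outward^2))
      outward <- if (no > 1e-8) outward / no else c(0, 0, 0)
      # persistent (near-extended) backbone: consecutive-residue native
      # contacts can only be avoided when the local chain is stretched
      gp <- parent[pa]
      prev_dir <- if (!is.na(gp) && !anyNA(pos[gp, ])) {
        .unit(pos[pa, ] - pos[gp, ])
      } else {
        outward
      }
      is_backbone <- structure$atoms$name[a] %in% c("P", "O5'", "C4'", "O3'")
      done <- FALSE
      for (try in seq_len(150)) {
        dir <- if (is_backbone) {
          # near-straight persistent walk: local extension is what breaks
          # the consecutive-residue native contacts
          .unit(6 * prev_dir + 0.3 * outward + (0.25 + 0.1 * try) *
                  stats::rnorm(3))
        } else if (structure$atoms$name[a] == "N1") {
          # base nitrogens lean against the chain direction, clearing the
          # downstream backbone (whose native contacts have the largest
          # avoidance radii)
          .unit(-0.5 * prev_dir + 0.9 * stats::rnorm(3))
        } else {
          # remaining base-ring atoms grow outward, away from the backbone
          .unit(1.2 * prev_dir + 0.8 * stats::rnorm(3))
        }
        x <- pos[pa, ] + blen * dir
        others <- setdiff(placed, bonded_to(a))
        if (length(others) > 0) {
          d2 <- rowSums((pos[others, , drop = FALSE] -
                         matrix(x, length(others), 3, byrow = TRUE))^2)
          if (any(d2 < 4.0)) next
        }
        pp <- partners[[a]]
        if (!is.null(pp)) {
          pl <- pp[pp[, 1] %in% placed, , drop = FALSE]
          if (nrow(pl) > 0) {
            d <- sqrt(rowSums((pos[pl[, 1], , drop = FALSE] -
                               matrix(x, nrow(pl), 3, byrow = TRUE))^2))
            if (any(d < pl[, 2])) next
          }
        }
        pos[a, ] <- x
        done <- TRUE
        break
      }
      if (done) {
        oi <- oi + 1L
      } else {
        # constraints often become infeasible a few placements upstream;
        # unwind locally before giving up on the whole chain
        backtracks <- backtracks + 1L
        if (backtracks > 400L) {
          ok_all <- FALSE
          break
        }
        oi_new <- max(2L, oi - 6L)
        pos[order_[seq(oi_new, oi)], ] <- NA_real_
        oi <- oi_new
      }
    }
    if (ok_all) {
      q <- compute_q(pos, cmap, lambda_formed = lambda_formed)
      if (q == 0) return(pos)
    }
  }
  stop("failed to generate a zero-contact unfolded configuration within ",
       max_restarts, " restarts")
}

#' Go parameters calibrated for the bundled pseudo-atom fixtures
#'
#' The toy fixtures carry roughly 1.3 native contacts per residue where a
#' full-atom tRNA carries ~40, so the per-contact well depth must be
#' renormalized for the folded state to be thermally stable at all: with
#' the full-atom default (0.14 kcal/mol) the toy's total native contact
#' energy is ~0.05 kcal/mol per residue and the fold is not even
#' metastable. `eps_native = 10` restores a per-residue native
#' stabilization of the same order as the full-atom system and yields
#' two-state behaviour for the hairpin: folded at 300 K, near melting at
#' 353 K, unfolded excursions below Q = 0.2 at 600 K. The four-arm toy
#' tRNA pays a larger assembly entropy, so its folding study uses
#' `eps_native = 18`, deep enough that complete assembly at 353 K occurs
#' within practical trajectory lengths. The non-native repulsion keeps
#' the 14:1 ratio of the full-atom parameterization.
#'
#' @param eps_native renormalized native well depth (kcal/mol); 10 for
#'   the hairpin fixture, 18 recommended for [make_mini_trna()] folding
#'   studies.
#' @param ... overrides forwarded to [go_parameters()].
#' @export
fixture_go_parameters <- function(eps_native = 10, ...) {
  go_parameters(eps_native = eps_native, eps_nonnative = eps_native / 14,
                ...)
}
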