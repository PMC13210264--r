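# Shared fixtures and independent oracles.

# a tiny two-residue structure with hand-placed atoms; coordinates chosen
# so all bonds are < 2 A
toy_structure <- function() {
  atoms <- data.frame(
    name = rep(c("P", "O5'", "C4'", "O3'", "N1"), 2),
    element = rep(c("P", "O", "C", "O", "N"), 2),
    residue_index = rep(1:2, each = 5),
    stringsAsFactors = FALSE
  )
  xyz <- rbind(
    c(0.0, 0.0, 0.0), c(1.1, 1.0, -0.3), c(2.3, 0.0, -0.7),
    c(3.3, 0.8, -0.2), c(2.3, 0.0, 0.8),
    c(3.8, 0.0, 0.0), c(4.9, 1.0, -0.3), c(6.1, 0.0, -0.7),
    c(7.1, 0.8, -0.2), c(6.1, 0.0, 0.8)
  )
  go_structure(atoms, xyz, c("A", "G"))
}

# independent all-pairs native-contact oracle (same rules as the builder,
# implemented by direct enumeration)
brute_force_contacts <- function(structure, cutoff = 4.0,
                                 include_intra_residue = FALSE,
                                 min_bond_sep = 6) {
  n <- nrow(structure$atoms)
  xyz <- structure$xyz
  bonds <- structure$bonds
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]
    j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  graph_dist <- function(a, b, maxd) {
    dist <- rep(Inf, n)
    dist[a] <- 0
    frontier <- a
    for (d in seq_len(maxd)) {
      frontier <- unique(unlist(adj[frontier]))
      frontier <- frontier[dist[frontier] == Inf]
      if (length(frontier) == 0) break
      dist[frontier] <- d
    }
    dist[b]
  }
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (r > cutoff) next
      if (!include_intra_residue &&
          structure$atoms$residue_index[i] ==
          structure$atoms$residue_index[j]) next
      gd <- graph_dist(i, j, max(min_bond_sep, 3))
      if (gd < min_bond_sep) next
      out[[length(out) + 1]] <- c(i, j)
    }
  }
  if (length(out) == 0) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

# numeric gradient of the total energy by central differences
numeric_force <- function(positions, structure, cmap, params, i, k,
                          h = 1e-5) {
  pp <- positions
  pp[i, k] <- pp[i, k] + h
  pm <- positions
  pm[i, k] <- pm[i, k] - h
  ep <- total_energy_forces(pp, structure, cmap, params)$total
  em <- total_energy_forces(pm, structure, cmap, params)$total
  -(ep - em) / (2 * h)
}

# a synthetic per-domain Q series data frame for classifier tests
scripted_series <- function(crossings, n_frames = 60, q_fold = 0.8) {
  df <- data.frame(time = seq_len(n_frames))
  for (nm in names(crossings)) {
    t0 <- crossings[[nm]]
    q <- rep(0.1, n_frames)
    if (is.finite(t0)) q[t0:n_frames] <- 0.95
    df[[paste0("q_", nm)]] <- q
  }
  df
}
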