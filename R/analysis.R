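# Order-parameter analyses: Q (global and per-domain), free-energy
# profiles F(Q), pathway classification, contact-frequency maps, base
# center-of-mass shifts and hydrogen-bond counts.

#' Fraction of native contacts Q
#'
#' `Q = (# contacts with r < lambda * sigma) / (total contacts)`. With the
#' optional `domain` argument only contacts whose two residues both lie in
#' the domain are counted (intra-domain Q).
#'
#' @param frame coordinate matrix, one row per atom.
#' @param cmap a `go_contact_map`.
#' @param lambda_formed formation multiplier (contact formed when
#'   r < lambda * sigma); default 1.2.
#' @param domain optional integer vector of residue indices restricting
#'   the contact set.
#' @param domain_name label used in the empty-set error message.
#' @return Q in \[0, 1\].
#' @export
compute_q <- function(frame, cmap, lambda_formed = 1.2, domain = NULL,
                      domain_name = NULL) {
  ct <- cmap$contacts
  if (!is.null(domain)) {
    keep <- ct$res_i %in% domain & ct$res_j %in% domain
    ct <- ct[keep, , drop = FALSE]
  }
  if (nrow(ct) == 0) {
    lbl <- if (!is.null(domain_name)) domain_name else
      if (!is.null(domain)) paste(range(domain), collapse = "-") else "global"
    stop("no native contacts in the restricted set (domain: ", lbl, ")")
  }
  frame <- as.matrix(frame)
  d2 <- rowSums((frame[ct$i, , drop = FALSE] -
                 frame[ct$j, , drop = FALSE])^2)
  mean(d2 < (lambda_formed * ct$sigma)^2)
}

#' Per-frame Q series (global and per-domain) for a trajectory
#'
#' @param trajectory a `go_trajectory`.
#' @param cmap a `go_contact_map`.
#' @param domains optional `go_domains` partition; adds one `q_<name>`
#'   column per domain (intra-domain contacts only).
#' @param lambda_formed formation multiplier.
#' @return data frame with `time`, `q` and per-domain columns; class
#'   `go_qseries`.
#' @export
q_series <- function(trajectory, cmap, domains = NULL,
                     lambda_formed = 1.2) {
  df <- data.frame(
    time = trajectory$times,
    q = vapply(trajectory$frames, compute_q, 0.0, cmap = cmap,
               lambda_formed = lambda_formed)
  )
  if (!is.null(domains)) {
    for (nm in names(domains)) {
      df[[paste0("q_", nm)]] <- vapply(
        trajectory$frames, compute_q, 0.0, cmap = cmap,
        lambda_formed = lambda_formed, domain = domains[[nm]],
        domain_name = nm
      )
    }
  }
  class(df) <- c("go_qseries", "data.frame")
  df
}

#' Free-energy profile F(Q) = -kB T ln P(Q)
#'
#' P(Q) is the normalized histogram of the pooled Q samples; F is shifted
#' so its minimum over occupied bins is zero; empty bins are `NA` (masked,
#' not smoothed).
#'
#' @param q_samples numeric vector of Q values in \[0, 1\].
#' @param temperature K.
#' @param n_bins number of equal-width bins over \[0, 1\] (default 20,
#'   i.e. bin width 0.05).
#' @return A `go_fq_profile`: list with `bin_edges`, `bin_mid`, `F`
#'   (kcal/mol, `NA` for empty bins) and `occupancy`.
#' @export
free_energy_profile <- function(q_samples, temperature, n_bins = 20) {
  if (length(q_samples) == 0) stop("empty Q sample set")
  if (any(q_samples < 0 | q_samples > 1)) stop("Q samples outside [0, 1]")
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(q_samples, edges, rightmost.closed = TRUE),
                   1L), n_bins)
  occ <- tabulate(bin, nbins = n_bins)
  p <- occ / sum(occ)
  f <- ifelse(occ > 0, -kB * temperature * log(p), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  structure(
    list(bin_edges = edges, bin_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
         F = f, occupancy = occ, temperature = temperature),
    class = "go_fq_profile"
  )
}

#' Classify the domain-folding pathway of one trajectory
#'
#' A domain's folding time is the first frame at which its Q exceeds
#' `q_fold` and stays above it for `persistence` consecutive frames
#' (transient spikes are ignored). The pathway label joins the domains in
#' order of folding time with arrows; ties are broken by domain name and
#' flagged.
#'
#' @param series a [q_series()] data frame with `q_<domain>` columns.
#' @param q_fold folding threshold (default 0.8).
#' @param persistence consecutive frames required above threshold.
#' @return A `go_pathway` list: `events` (data frame `domain`, `time`,
#'   `frame`), `label` (e.g. `"asl->tsl->dsl"`, or `"none"`), `tie`.
#' @export
classify_pathway <- function(series, q_fold = 0.8, persistence = 5) {
  qcols <- grep("^q_", names(series), value = TRUE)
  if (length(qcols) == 0) stop("series has no per-domain q_ columns")
  if (nrow(series) < persistence) {
    stop("series shorter than the persistence window")
  }
  events <- list()
  for (col in qcols) {
    above <- series[[col]] > q_fold
    idx <- NA_integer_
    run <- 0L
    for (t in seq_along(above)) {
      run <- if (above[t]) run + 1L else 0L
      # a run may also persist through the trajectory end
      if (run >= persistence) {
        idx <- t - persistence + 1L
        break
      }
    }
    if (is.na(idx) && run > 0 && run == sum(utils::tail(above, run))) {
      idx <- NA_integer_ # ended above threshold but without persistence
    }
    if (!is.na(idx)) {
      events[[length(events) + 1]] <- data.frame(
        domain = sub("^q_", "", col), time = series$time[idx], frame = idx,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(events) == 0) {
    return(structure(list(events = data.frame(domain = character(0),
                                              time = numeric(0),
                                              frame = integer(0)),
                          label = "none", tie = FALSE),
                     class = "go_pathway"))
  }
  ev <- do.call(rbind, events)
  tie <- anyDuplicated(ev$time) > 0
  ev <- ev[order(ev$time, ev$domain), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev, label = paste(ev$domain, collapse = "->"),
                 tie = tie),
            class = "go_pathway")
}

#' Pathway fractions over an ensemble
#'
#' @param labels character vector of pathway labels, or a list of
#'   `go_pathway` objects.
#' @return An `go_ensemble_summary`: `fractions` (named percentages,
#'   summing to 100 over observed labels), `counts`, `per_trajectory`.
#' @export
pathway_fractions <- function(labels) {
  if (is.list(labels)) {
    labels <- vapply(labels, function(x) {
      if (inherits(x, "go_pathway")) x$label else as.character(x)
    }, "")
  }
  if (length(labels) == 0) stop("empty ensemble")
  counts <- table(labels)
  structure(
    list(fractions = 100 * as.vector(counts) / length(labels),
         counts = as.vector(counts), labels = names(counts),
         per_trajectory = labels),
    class = "go_ensemble_summary"
  )
}

#' @export
print.go_ensemble_summary <- function(x, ...) {
  cat("Folding pathway ensemble (", length(x$per_trajectory),
      " trajectories):\n", sep = "")
  for (k in order(-x$fractions)) {
    cat(sprintf("  %-30s %5.1f%%  (n = %d)\n", x$labels[k], x$fractions[k],
                x$counts[k]))
  }
  invisible(x)
}

#' Residue-residue contact formation frequency map
#'
#' Entry (a, b) is the fraction of trajectory frames in which at least one
#' native atom contact between residues a and b is formed.
#'
#' @param trajectory a `go_trajectory` (or list of frames).
#' @param cmap a `go_contact_map`.
#' @param n_residues matrix dimension; inferred from the contacts when
#'   missing.
#' @param lambda_formed formation multiplier.
#' @return symmetric numeric matrix with values in \[0, 1\].
#' @export
contact_frequency_map <- function(trajectory, cmap, n_residues = NULL,
                                  lambda_formed = 1.2) {
  frames <- if (inherits(trajectory, "go_trajectory")) trajectory$frames
            else trajectory
  if (length(frames) == 0) stop("empty trajectory")
  ct <- cmap$contacts
  if (is.null(n_residues)) n_residues <- max(ct$res_i, ct$res_j)
  pair_id <- factor(paste(ct$res_i, ct$res_j))
  acc <- numeric(nlevels(pair_id))
  thr2 <- (lambda_formed * ct$sigma)^2
  for (fr in frames) {
    d2 <- rowSums((fr[ct$i, , drop = FALSE] - fr[ct$j, , drop = FALSE])^2)
    formed <- d2 < thr2
    acc <- acc + (tapply(formed, pair_id, any) > 0)
  }
  freq <- acc / length(frames)
  m <- matrix(0, n_residues, n_residues)
  key <- do.call(rbind, strsplit(levels(pair_id), " "))
  a <- as.integer(key[, 1])
  b <- as.integer(key[, 2])
  m[cbind(a, b)] <- freq
  m[cbind(b, a)] <- freq
  m
}

#' Two-dimensional Q histogram (e.g. Q_tsl vs Q_dsl)
#'
#' @param qx,qy Q samples for the two domains (equal length).
#' @param n_bins bins per axis.
#' @return list with `counts` (matrix), `edges`, `mids`.
#' @export
q2d_histogram <- function(qx, qy, n_bins = 10) {
  stopifnot(length(qx) == length(qy))
  edges <- seq(0, 1, length.out = n_bins + 1)
  bx <- pmin(pmax(findInterval(qx, edges, rightmost.closed = TRUE), 1L),
             n_bins)
  by <- pmin(pmax(findInterval(qy, edges, rightmost.closed = TRUE), 1L),
             n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (k in seq_along(bx)) counts[bx[k], by[k]] <- counts[bx[k], by[k]] + 1L
  list(counts = counts, edges = edges,
       mids = (edges[-1] + edges[-(n_bins + 1)]) / 2)
}

#' Corner vs diagonal mass of a 2-D Q histogram
#'
#' Operationalizes the sequential-folding signature: trajectories that fold
#' two domains one after the other populate the off-diagonal corners
#' (one Q high while the other is still low), whereas concomitant folding
#' populates the central diagonal. Corner bins: one coordinate > 0.8 and
#' the other < 0.2. Diagonal bins: |qx - qy| <= 0.2 with mean coordinate
#' strictly between 0.2 and 0.8 (the transition region; the trivial
#' unfolded and folded end bins are not counted).
#'
#' @param hist2d output of [q2d_histogram()].
#' @return list with `corner_mass` and `diagonal_mass` (fractions of all
#'   samples).
#' @export
corner_diagonal_mass <- function(hist2d) {
  mids <- hist2d$mids
  total <- sum(hist2d$counts)
  corner <- 0
  diagonal <- 0
  for (a in seq_along(mids)) {
    for (b in seq_along(mids)) {
      x <- mids[a]
      y <- mids[b]
      if ((x > 0.8 && y < 0.2) || (x < 0.2 && y > 0.8)) {
        corner <- corner + hist2d$counts[a, b]
      } else if (abs(x - y) <= 0.2 && (x + y) / 2 > 0.2 &&
                 (x + y) / 2 < 0.8) {
        diagonal <- diagonal + hist2d$counts[a, b]
      }
    }
  }
  list(corner_mass = corner / total, diagonal_mass = diagonal / total)
}

.base_com <- function(frame, structure, residue) {
  sel <- structure$atoms$residue_index == residue & structure$atoms$base_atom
  if (!any(sel)) stop("residue ", residue, " has no base atoms")
  w <- structure$atoms$mass[sel]
  colSums(frame[sel, , drop = FALSE] * w) / sum(w)
}

.gate_frames <- function(trajs, cmap, domains, gate, lambda) {
  out <- list()
  for (tr in trajs) {
    frames <- if (inherits(tr, "go_trajectory")) tr$frames else tr
    for (fr in frames) {
      ok <- TRUE
      for (nm in names(gate)) {
        qd <- compute_q(fr, cmap, lambda_formed = lambda,
                        domain = domains[[nm]], domain_name = nm)
        if (qd < gate[[nm]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) out[[length(out) + 1]] <- fr
    }
  }
  out
}

#' Base center-of-mass distance shift between modified and unmodified
#' ensembles
#'
#' For each system, frames are gated on per-domain Q conditions (folded
#' "relevant structural domains"); over the gated frames the mass-weighted
#' base-atom center-of-mass distance between the focus residue and a
#' neighbour residue is averaged. `delta = d_modified - d_unmodified`;
#' negative values mean the residues sit closer in the modified system.
#'
#' @param trajs_mod,trajs_unmod lists of `go_trajectory` for the modified
#'   and unmodified systems.
#' @param structure_mod,structure_unmod the two structures.
#' @param cmap_mod,cmap_unmod their contact maps.
#' @param domains a `go_domains` partition (residue numbering shared by
#'   both systems).
#' @param focus_residue,neighbor_residue residue indices.
#' @param gate named numeric vector of per-domain minimum Q values, e.g.
#'   `c(asl = 0.8, dsl = 0.8)`.
#' @param lambda_formed formation multiplier.
#' @return list with `d_modified`, `d_unmodified`, `delta` (angstrom) and
#'   gated frame counts.
#' @export
base_com_delta <- function(trajs_mod, trajs_unmod, structure_mod,
                           structure_unmod, cmap_mod, cmap_unmod, domains,
                           focus_residue, neighbor_residue,
                           gate = NULL, lambda_formed = 1.2) {
  mean_d <- function(trajs, structure, cmap) {
    frames <- if (is.null(gate)) {
      unlist(lapply(trajs, function(tr) {
        if (inherits(tr, "go_trajectory")) tr$frames else tr
      }), recursive = FALSE)
    } else {
      .gate_frames(trajs, cmap, domains, gate, lambda_formed)
    }
    if (length(frames) == 0) {
      stop("no frames satisfy the gate (",
           paste(names(gate), ">=", gate, collapse = ", "), ")")
    }
    d <- vapply(frames, function(fr) {
      sqrt(sum((.base_com(fr, structure, focus_residue) -
                .base_com(fr, structure, neighbor_residue))^2))
    }, 0.0)
    list(mean = mean(d), n = length(frames))
  }
  m <- mean_d(trajs_mod, structure_mod, cmap_mod)
  u <- mean_d(trajs_unmod, structure_unmod, cmap_unmod)
  list(d_modified = m$mean, d_unmodified = u$mean, delta = m$mean - u$mean,
       n_frames_modified = m$n, n_frames_unmodified = u$n)
}

#' Count base-base hydrogen bonds between two residues
#'
#' Heavy-atom criterion: a donor atom of one base within `cutoff`
#' (default 3.5 angstrom) of an acceptor atom of the other. A pair
#' qualifying in both directions is counted once. Hydrogens and angles are
#' not used (the model is heavy-atom only). Note the m2,2G base contributes
#' no N2 donor: both amine positions carry methyls.
#'
#' @param frame coordinate matrix.
#' @param structure a [go_structure()].
#' @param res_a,res_b residue indices.
#' @param cutoff donor-acceptor distance cutoff (angstrom).
#' @return integer hydrogen-bond count.
#' @export
hbond_count <- function(frame, structure, res_a, res_b, cutoff = 3.5) {
  get_da <- function(res) {
    base <- structure$residues$base[res]
    sel <- which(structure$atoms$residue_index == res)
    nm <- structure$atoms$name[sel]
    list(d = sel[nm %in% .HB_DONORS[[base]]],
         a = sel[nm %in% .HB_ACCEPTORS[[base]]])
  }
  A <- get_da(res_a)
  B <- get_da(res_b)
  if (length(c(A$d, A$a)) == 0 || length(c(B$d, B$a)) == 0) {
    message("residue ", res_a, " or ", res_b,
            " has no donor/acceptor atoms; hydrogen-bond count is 0")
    return(0L)
  }
  pairs <- rbind(
    expand.grid(i = A$d, j = B$a),
    expand.grid(i = A$a, j = B$d)
  )
  if (nrow(pairs) == 0) return(0L)
  key <- paste(pmin(pairs$i, pairs$j), pmax(pairs$i, pairs$j))
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  d <- sqrt(rowSums((frame[pairs$i, , drop = FALSE] -
                     frame[pairs$j, , drop = FALSE])^2))
  sum(d < cutoff)
}
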