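# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use different derivations from the implementation
# they check.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# dihedral by projection onto the plane perpendicular to the central
# bond: signed angle from the i-side projection to the l-side projection
# about the j->k axis.
oracle_dihedral <- function(p) {
  b2 <- p[3, ] - p[2, ]
  b2 <- b2 / sqrt(sum(b2^2))
  u <- p[1, ] - p[2, ]
  u <- u - sum(u * b2) * b2
  v <- p[4, ] - p[3, ]
  v <- v - sum(v * b2) * b2
  ang <- atan2(sum(.cross3(u, v) * b2), sum(u * v)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# brute-force rotation-grid search for the optimal superposition RMSD:
# coarse scan over z-y-z Euler angles followed by local refinement.
oracle_superpose_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  rot <- function(a, b, c) {
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
    Rz(a) %*% Ry(b) %*% Rz(c)
  }
  eval_rmsd <- function(a, b, c) {
    R <- rot(a, b, c)
    sqrt(mean(rowSums((Q0 %*% t(R) - P0)^2)))
  }
  best <- c(0, 0, 0)
  best_val <- Inf
  step <- pi / 18  # 10 degrees
  grid_a <- seq(0, 2 * pi - step, by = step)
  grid_b <- seq(0, pi, by = step)
  for (a in grid_a) for (b in grid_b) for (c in grid_a) {
    v <- eval_rmsd(a, b, c)
    if (v < best_val) { best_val <- v; best <- c(a, b, c) }
  }
  for (round in 1:3) {
    step <- step / 3
    cand <- expand.grid(
      a = best[1] + step * (-4:4),
      b = best[2] + step * (-4:4),
      c = best[3] + step * (-4:4)
    )
    for (i in seq_len(nrow(cand))) {
      v <- eval_rmsd(cand$a[i], cand$b[i], cand$c[i])
      if (v < best_val) {
        best_val <- v
        best <- as.numeric(cand[i, ])
      }
    }
  }
  # simplex polish of the best grid point (still independent of the
  # closed-form solution under test)
  pol <- stats::optim(best, function(p) eval_rmsd(p[1], p[2], p[3]),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  min(best_val, pol$value)
}

# random valid frcmod documents for round-trip checks
random_frcmod <- function(seed) {
  withr::with_seed(seed, {
    pool <- c("aa", "ab", "ba", "bb", "ca", "cb", "da", "db", "ea", "eb",
              "fa", "fb", "ga", "gb")
    ntypes <- sample(4:8, 1)
    types <- sample(pool, ntypes)
    mass <- data.frame(
      atom_type = types,
      mass = round(runif(ntypes, 1, 40), 3),
      polarizability = round(runif(ntypes, 0.1, 1), 3),
      stringsAsFactors = FALSE
    )
    nb <- data.frame(
      atom_type = types, mass = mass$mass,
      polarizability = mass$polarizability,
      r_star = round(runif(ntypes, 1, 2.2), 4),
      epsilon = round(runif(ntypes, 0.01, 0.3), 4),
      stringsAsFactors = FALSE
    )
    # unique canonical bond keys
    pairs <- expand.grid(a1 = types, a2 = types, stringsAsFactors = FALSE)
    key <- ifelse(paste(pairs$a1, pairs$a2) <= paste(pairs$a2, pairs$a1),
                  paste(pairs$a1, pairs$a2), paste(pairs$a2, pairs$a1))
    pairs <- pairs[!duplicated(key), ]
    pairs <- pairs[sample(nrow(pairs), min(6, nrow(pairs))), ]
    bonds <- data.frame(
      a1 = pairs$a1, a2 = pairs$a2,
      k_r = round(runif(nrow(pairs), 100, 700), 1),
      r_eq = round(runif(nrow(pairs), 0.9, 1.9), 4),
      source = paste0("rand", seq_len(nrow(pairs))),
      stringsAsFactors = FALSE
    )
    tri <- data.frame(
      a1 = sample(types, 4, replace = TRUE),
      a2 = types[1:4 %% ntypes + 1],
      a3 = sample(types, 4, replace = TRUE),
      stringsAsFactors = FALSE
    )
    tk <- xfpchromo:::.canonical_tuple(tri$a1, tri$a2, tri$a3)
    tri <- tri[!duplicated(tk), ]
    angles <- data.frame(
      a1 = tri$a1, a2 = tri$a2, a3 = tri$a3,
      k_theta = round(runif(nrow(tri), 30, 90), 3),
      theta_eq = round(runif(nrow(tri), 100, 130), 3),
      source = paste0("rand", seq_len(nrow(tri))),
      stringsAsFactors = FALSE
    )
    # one wildcard torsion plus one 2-term explicit torsion
    torsions <- data.frame(
      a1 = c("X", types[1], types[1]),
      a2 = c(types[1], types[2], types[2]),
      a3 = c(types[2], types[3], types[3]),
      a4 = c("X", types[4], types[4]),
      paths_divisor = c(sample(c(2L, 4L), 1), 1L, 1L),
      half_barrier = round(runif(3, 0, 16), 3),
      phase = c(180, 0, 180),
      periodicity = c(2L, 3L, 1L),
      source = c("randw", "randt", "component 2"),
      group = c(1L, 2L, 2L),
      stringsAsFactors = FALSE
    )
    impropers <- data.frame(
      a1 = "X", a2 = "X", a3 = types[1], a4 = types[2],
      half_barrier = sample(c(10.5, 1.1), 1), phase = 180,
      periodicity = 2L, source = "rand",
      stringsAsFactors = FALSE
    )
    frcmod_document(
      title = paste("random document", seed),
      mass = mass, bonds = bonds, angles = angles, torsions = torsions,
      impropers = impropers, nonbonded = nb
    )
  })
}

# charges consistent with a scheme's constraints so that noise-free
# generator recovery remains exact under the constrained fit
make_recoverable_charges <- function(topo, total = 0,
                                     scheme = c("free", "cap", "amide"),
                                     seed = 1) {
  scheme <- match.arg(scheme)
  withr::with_seed(seed, {
    n <- n_atoms(topo)
    q <- rnorm(n, 0, 0.3)
    for (g in xfpchromo:::.ch_groups(topo)) {
      q[g$hydrogens] <- mean(q[g$hydrogens])
    }
    atoms <- topo$atoms
    at <- function(name) which(atoms$name == name)
    if (scheme == "amide") {
      ref <- consensus_terminal_charges()
      q[at("C")] <- ref[["C"]]
      q[at("O")] <- ref[["O"]]
      if ("HN" %in% atoms$name) {
        q[at("N")] <- ref[["N"]]
        q[at("HN")] <- ref[["H"]]
      } else {
        q[at("CY")] <- ref[["C"]]
        q[at("OY")] <- ref[["O"]]
      }
    }
    if (scheme %in% c("cap", "amide")) {
      ace <- which(atoms$role == "cap_ACE")
      nme <- which(atoms$role == "cap_NME")
      q[at("CAY")] <- q[at("CAY")] - sum(q[ace])
      q[at("NT")] <- q[at("NT")] - sum(q[nme])
    }
    q[at("CA")] <- q[at("CA")] - (sum(q) - total)
    q
  })
}

# well-separated random atom positions (Bohr) for ESP fixtures
random_positions <- function(n, seed, spacing = 3) {
  withr::with_seed(seed, {
    pos <- matrix(rnorm(3 * n, sd = spacing), n, 3)
    repeat {
      if (n == 1) break
      d <- as.matrix(dist(pos))
      diag(d) <- Inf
      worst <- which(d < 2, arr.ind = TRUE)
      if (!nrow(worst)) break
      i <- worst[1, 1]
      pos[i, ] <- rnorm(3, sd = spacing)
    }
    pos
  })
}
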