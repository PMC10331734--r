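# Deterministic, seedable synthetic fixtures carrying the statistical
# and geometric structure the other modules assume.  All generators are
# pure functions of (inputs, seed).

#' Synthetic ESP grid around known point charges
#'
#' Places grid points on shells at the given multipliers of each atom's
#' nominal radius (uniform random directions), evaluates the Coulomb
#' potential of the supplied charges at each point, and optionally adds
#' Gaussian noise.  The default shell multipliers (1.4, 1.6, 1.8, 2.0)
#' echo standard ESP-grid practice.
#'
#' @param charges length-n charges (e).
#' @param positions n x 3 atom positions (Bohr).
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @param shells radii multipliers (> 1).
#' @param points_per_shell grid points per shell per atom.
#' @param radii per-atom nominal radii (Bohr).
#' @param noise_sd Gaussian noise SD added to the potentials (au).
#' @return an [esp_grid].
#' @export
gen_esp_fixture <- function(charges, positions, seed,
                            shells = c(1.4, 1.6, 1.8, 2.0),
                            points_per_shell = 8L,
                            radii = rep(3.0, length(charges)),
                            noise_sd = 0) {
  positions <- as.matrix(positions)
  n <- length(charges)
  stopifnot(nrow(positions) == n, length(radii) == n, all(shells > 1))
  withr::with_seed(seed, {
    pts <- list()
    for (i in seq_len(n)) {
      for (s in shells) {
        # uniform directions on the sphere
        z <- runif(points_per_shell, -1, 1)
        phi <- runif(points_per_shell, 0, 2 * pi)
        r <- sqrt(1 - z^2)
        dirs <- cbind(r * cos(phi), r * sin(phi), z)
        pts[[length(pts) + 1L]] <-
          sweep(dirs * (s * radii[i]), 2L, positions[i, ], `+`)
      }
    }
    grid_points <- do.call(rbind, pts)
    # drop points that fall inside another atom's nominal radius, so the
    # minimum-distance invariant always holds with margin
    d <- .atom_point_dists(positions, grid_points)
    keep <- apply(d, 1L, min) > 1.0
    grid_points <- grid_points[keep, , drop = FALSE]
    pot <- esp_from_point_charges(charges, positions, grid_points)
    if (noise_sd > 0) pot <- pot + rnorm(length(pot), 0, noise_sd)
    esp_grid(positions, grid_points, pot)
  })
}

#' Synthetic capped-residue topology
#'
#' Builds a chemically plausible capped fragment: an acetyl (ACE) cap
#' (methyl + carbonyl C/O), an amide nitrogen with or without its
#' hydrogen, a central alpha-carbon fragment with an optional sidechain
#' chain (terminal methyl, internal methylenes), a chromophore carbonyl
#' C/O, and an N-methyl-amide (NME) cap.  All role and terminal-flag
#' annotations are set; bonds are explicit; coordinates are a jittered
#' zig-zag chain (seeded), so two seeds share the topology but differ
#' in geometry.
#'
#' @param n_sidechain_atoms number of sidechain carbons (0 for none;
#'   the last carbon of a nonempty chain is a methyl).
#' @param with_amide_h if `FALSE`, the amino terminus is proline-like
#'   (no amide hydrogen), as in the DsRed/mCherry chromophores.
#' @param seed integer seed.
#' @return an annotated [xfp_structure].
#' @export
gen_capped_topology <- function(n_sidechain_atoms = 1L, with_amide_h = TRUE,
                                seed = 1L) {
  atoms <- list()
  bonds <- list()
  add_atom <- function(name, element, role, flag = "none") {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, element = element, atom_type = NA_character_,
      role = role, terminal_flag = flag, stringsAsFactors = FALSE
    )
    length(atoms)
  }
  add_bond <- function(i, j) bonds[[length(bonds) + 1L]] <<- c(i, j)

  # ACE cap: CH3-C(=O)-
  cay <- add_atom("CAY", "C", "cap_ACE")
  for (h in 1:3) add_bond(cay, add_atom(paste0("HY", h), "H", "cap_ACE"))
  cy <- add_atom("CY", "C", "cap_ACE", "carbonyl_C")
  oy <- add_atom("OY", "O", "cap_ACE", "carbonyl_O")
  add_bond(cay, cy); add_bond(cy, oy)

  # amide N (+H), alpha carbon
  n1 <- add_atom("N", "N", "chromophore", "amide_N")
  add_bond(cy, n1)
  if (with_amide_h) add_bond(n1, add_atom("HN", "H", "chromophore", "amide_H"))
  ca <- add_atom("CA", "C", "chromophore")
  ha <- add_atom("HA", "H", "chromophore")
  add_bond(n1, ca); add_bond(ca, ha)

  # sidechain: internal methylenes, terminal methyl
  prev <- ca
  if (n_sidechain_atoms > 0L) {
    for (k in seq_len(n_sidechain_atoms)) {
      cb <- add_atom(paste0("CS", k), "C", "chromophore")
      add_bond(prev, cb)
      nh <- if (k == n_sidechain_atoms) 3L else 2L
      for (h in seq_len(nh)) {
        add_bond(cb, add_atom(paste0("HS", k, h), "H", "chromophore"))
      }
      prev <- cb
    }
  }

  # chromophore carbonyl
  cc_ <- add_atom("C", "C", "chromophore", "carbonyl_C")
  oc <- add_atom("O", "O", "chromophore", "carbonyl_O")
  add_bond(ca, cc_); add_bond(cc_, oc)

  # NME cap: -NH-CH3
  nt <- add_atom("NT", "N", "cap_NME")
  hnt <- add_atom("HNT", "H", "cap_NME")
  cat_ <- add_atom("CAT", "C", "cap_NME")
  add_bond(cc_, nt); add_bond(nt, hnt); add_bond(nt, cat_)
  for (h in 1:3) add_bond(cat_, add_atom(paste0("HT", h), "H", "cap_NME"))

  atoms <- do.call(rbind, atoms)
  bonds <- do.call(rbind, bonds)
  n <- nrow(atoms)
  coords <- withr::with_seed(seed, {
    # zig-zag backbone with ~1.5 A steps plus jitter
    base <- cbind(1.5 * seq_len(n), 0.8 * (seq_len(n) %% 2L), 0)
    base + matrix(rnorm(3L * n, sd = 0.3), n, 3L)
  })
  xfp_structure(atoms, coords, bonds)
}

#' Stationary autocorrelated angle series
#'
#' First-order autoregressive (AR(1)) series with the requested marginal
#' mean and SD: `x_t = center + rho (x_{t-1} - center) + eps_t` with
#' `eps_t ~ N(0, sigma sqrt(1 - rho^2))`, initialized from the marginal
#' distribution.  A stand-in for thermally fluctuating MD angle series.
#'
#' @param center marginal mean (degrees).
#' @param sigma marginal SD (degrees, >= 0).
#' @param autocorrelation lag-1 autocorrelation `rho` in [0, 1).
#' @param n series length.
#' @param seed integer seed.
#' @return numeric vector of length `n` (degrees).
#' @export
gen_ou_angle_series <- function(center, sigma, autocorrelation, n, seed) {
  stopifnot(autocorrelation >= 0, autocorrelation < 1, sigma >= 0, n >= 1L)
  if (sigma == 0) return(rep(center, n))
  withr::with_seed(seed, {
    x <- numeric(n)
    x[1L] <- rnorm(1L, center, sigma)
    if (n > 1L) {
      innov_sd <- sigma * sqrt(1 - autocorrelation^2)
      eps <- rnorm(n - 1L, 0, innov_sd)
      for (t in 2:n) {
        x[t] <- center + autocorrelation * (x[t - 1L] - center) + eps[t - 1L]
      }
    }
    x
  })
}

#' Perturbed copy of a structure
#'
#' Jitters every coordinate of every frame with seeded isotropic
#' Gaussian noise; an SD of 0 returns an identical copy.
#'
#' @param base an [xfp_structure].
#' @param displacement_sd per-axis displacement SD (Angstrom, >= 0).
#' @param seed integer seed.
#' @return a perturbed [xfp_structure].
#' @export
gen_perturbed_structure <- function(base, displacement_sd, seed) {
  stopifnot(displacement_sd >= 0)
  if (displacement_sd == 0) return(base)
  withr::with_seed(seed, {
    base$frames <- lapply(base$frames, function(fr) {
      fr + matrix(rnorm(length(fr), sd = displacement_sd),
                  nrow(fr), ncol(fr))
    })
    base
  })
}
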