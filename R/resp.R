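# Constrained two-stage restrained-ESP (RESP) charge fitting.
# All ESP quantities are in atomic units: positions in Bohr, potentials
# in hartree per elementary charge; fitted charges in elementary charges.

#' Construct an ESP grid
#'
#' @param atom_positions n x 3 matrix, Bohr.
#' @param grid_points m x 3 matrix, Bohr.
#' @param potentials length-m numeric, hartree/e.
#' @return object of class `esp_grid`.
#' @export
esp_grid <- function(atom_positions, grid_points, potentials) {
  atom_positions <- as.matrix(atom_positions)
  grid_points <- as.matrix(grid_points)
  stopifnot(ncol(atom_positions) == 3L, ncol(grid_points) == 3L,
            nrow(grid_points) == length(potentials))
  dmin <- min(.atom_point_dists(atom_positions, grid_points))
  if (dmin <= 1e-6) {
    stop("grid point coincides with an atom position (min distance ",
         format(dmin), " Bohr)")
  }
  structure(
    list(atom_positions = atom_positions, grid_points = grid_points,
         potentials = as.numeric(potentials)),
    class = "esp_grid"
  )
}

#' @export
print.esp_grid <- function(x, ...) {
  cat(sprintf("<esp_grid> %d atoms, %d grid points (atomic units)\n",
              nrow(x$atom_positions), nrow(x$grid_points)))
  invisible(x)
}

# m x n matrix of distances from each grid point to each atom
.atom_point_dists <- function(atoms, points) {
  m <- nrow(points); n <- nrow(atoms)
  d <- matrix(0, m, n)
  for (i in seq_len(n)) {
    d[, i] <- sqrt((points[, 1L] - atoms[i, 1L])^2 +
                   (points[, 2L] - atoms[i, 2L])^2 +
                   (points[, 3L] - atoms[i, 3L])^2)
  }
  d
}

#' Electrostatic potential of point charges (forward model)
#'
#' Coulomb sum in atomic units: V(r) = sum_i q_i / |r - r_i|.
#'
#' @param charges length-n charges (e).
#' @param atom_positions n x 3 matrix (Bohr).
#' @param grid_points m x 3 matrix (Bohr).
#' @return length-m potentials (hartree/e).
#' @export
esp_from_point_charges <- function(charges, atom_positions, grid_points) {
  atom_positions <- as.matrix(atom_positions)
  grid_points <- as.matrix(grid_points)
  stopifnot(nrow(atom_positions) == length(charges))
  d <- .atom_point_dists(atom_positions, grid_points)
  if (min(d) <= 1e-6) stop("grid point coincides with an atom position")
  as.vector((1 / d) %*% charges)
}

#' RESP configuration
#'
#' Restraint defaults follow the standard two-stage RESP methodology:
#' weak hyperbolic restraint a1 = 0.0005 au in stage 1, stronger
#' a2 = 0.001 au in stage 2, restraint width b = 0.1 au, hydrogens
#' unrestrained.
#'
#' @param restraint_a_stage1,restraint_a_stage2 restraint strengths (au).
#' @param restraint_b restraint width (au).
#' @param restrain_hydrogens apply the restraint to hydrogens too.
#' @param convergence_tol iteration stops when max |dq| falls below this (e).
#' @param max_iterations iteration cap.
#' @return object of class `resp_config`.
#' @export
resp_config <- function(restraint_a_stage1 = 0.0005,
                        restraint_a_stage2 = 0.001,
                        restraint_b = 0.1,
                        restrain_hydrogens = FALSE,
                        convergence_tol = 1e-6,
                        max_iterations = 200L) {
  stopifnot(restraint_a_stage1 >= 0, restraint_a_stage2 >= 0,
            restraint_b > 0, convergence_tol > 0, max_iterations >= 1L)
  structure(
    list(restraint_a_stage1 = restraint_a_stage1,
         restraint_a_stage2 = restraint_a_stage2,
         restraint_b = restraint_b,
         restrain_hydrogens = isTRUE(restrain_hydrogens),
         convergence_tol = convergence_tol,
         max_iterations = as.integer(max_iterations)),
    class = "resp_config"
  )
}

# constraint constructors ------------------------------------------------

#' Charge constraints
#'
#' `charge_fix` pins one atom to a value; `charge_group_sum` constrains
#' the summed charge of a group; `charge_equivalence` forces a set of
#' atoms to share one charge.
#'
#' @param atoms 1-based atom indices.
#' @param value target charge (e) for fix / group-sum constraints.
#' @return a `charge_constraint` list.
#' @export
charge_fix <- function(atoms, value) {
  stopifnot(length(atoms) == 1L, is.finite(value))
  structure(list(kind = "fix", atoms = as.integer(atoms), value = value),
            class = "charge_constraint")
}

#' @rdname charge_fix
#' @export
charge_group_sum <- function(atoms, value) {
  stopifnot(length(atoms) >= 1L, is.finite(value))
  structure(list(kind = "group_sum", atoms = as.integer(atoms), value = value),
            class = "charge_constraint")
}

#' @rdname charge_fix
#' @export
charge_equivalence <- function(atoms) {
  stopifnot(length(atoms) >= 2L)
  structure(list(kind = "equivalence", atoms = as.integer(atoms), value = NA_real_),
            class = "charge_constraint")
}

#' Solve one restrained-ESP stage
#'
#' Minimizes `sum_points (V - sum_i q_i/r_i)^2 +
#' sum_i a (sqrt(q_i^2 + b^2) - b)` over non-frozen atoms subject to the
#' linear constraints (fix, group-sum, equivalence, total charge), via
#' iterated linear solves of the restrained normal equations with
#' Lagrange constraint rows.  Iterates until `max |dq| <` the
#' convergence tolerance.
#'
#' @param grid an [esp_grid].
#' @param total_charge total molecular charge (e), or `NA` to omit the
#'   total-charge constraint.
#' @param constraints list of [charge_fix()] / [charge_group_sum()] /
#'   [charge_equivalence()] constraints.
#' @param restraint_a hyperbolic restraint strength (au).
#' @param restraint_b restraint width (au).
#' @param frozen named numeric vector: names are atom indices, values
#'   the frozen charges (excluded from the fit).
#' @param elements optional element symbols (needed to leave hydrogens
#'   unrestrained).
#' @param config a [resp_config()].
#' @return numeric vector of all atom charges (frozen values included),
#'   with attribute `iterations`.
#' @export
resp_solve_stage <- function(grid, total_charge = NA, constraints = list(),
                             restraint_a = 0, restraint_b = 0.1,
                             frozen = NULL, elements = NULL,
                             config = resp_config()) {
  n <- nrow(grid$atom_positions)
  q <- numeric(n)
  frozen_idx <- integer()
  if (!is.null(frozen) && length(frozen)) {
    frozen_idx <- as.integer(names(frozen))
    q[frozen_idx] <- as.numeric(frozen)
  }
  # fix constraints behave as frozen charges: satisfied exactly
  for (con in constraints) {
    if (con$kind == "fix") {
      i <- con$atoms
      if (i %in% frozen_idx && abs(q[i] - con$value) > 1e-12) {
        stop("atom ", i, " frozen and fixed to conflicting values")
      }
      frozen_idx <- union(frozen_idx, i)
      q[i] <- con$value
    }
  }
  fixed_twice <- constraints[vapply(constraints, function(c) c$kind == "fix", TRUE)]
  fixed_atoms <- vapply(fixed_twice, function(c) c$atoms, 1L)
  if (anyDuplicated(fixed_atoms)) {
    vals <- split(vapply(fixed_twice, function(c) c$value, 1),
                  fixed_atoms)
    for (a in names(vals)) {
      if (length(unique(vals[[a]])) > 1L) {
        stop("atom ", a, " fixed to two different values")
      }
    }
  }
  free <- setdiff(seq_len(n), frozen_idx)
  if (!length(free)) {
    attr(q, "iterations") <- 0L
    return(q)
  }
  d <- .atom_point_dists(grid$atom_positions, grid$grid_points)
  Dinv <- 1 / d
  Vres <- grid$potentials
  if (length(frozen_idx)) {
    Vres <- Vres - as.vector(Dinv[, frozen_idx, drop = FALSE] %*% q[frozen_idx])
  }
  Df <- Dinv[, free, drop = FALSE]
  A <- crossprod(Df)
  bvec <- crossprod(Df, Vres)
  nf <- length(free)

  # constraint rows over the free atoms
  crows <- list(); cvals <- numeric()
  add_row <- function(row, val) {
    crows[[length(crows) + 1L]] <<- row
    cvals[length(cvals) + 1L] <<- val
  }
  if (!is.na(total_charge)) {
    add_row(rep(1, nf), total_charge - sum(q[frozen_idx]))
  }
  for (con in constraints) {
    if (con$kind == "group_sum") {
      in_free <- match(con$atoms, free)
      row <- numeric(nf)
      row[in_free[!is.na(in_free)]] <- 1
      val <- con$value - sum(q[con$atoms[is.na(in_free)]])
      if (any(row != 0)) add_row(row, val)
    } else if (con$kind == "equivalence") {
      idx <- match(con$atoms, free)
      if (anyNA(idx)) {
        stop("equivalence class contains frozen atom(s): ",
             paste(con$atoms[is.na(idx)], collapse = ", "))
      }
      for (j in idx[-1L]) {
        row <- numeric(nf)
        row[idx[1L]] <- 1; row[j] <- -1
        add_row(row, 0)
      }
    }
  }
  C <- if (length(crows)) do.call(rbind, crows) else matrix(0, 0L, nf)
  nc <- nrow(C)

  restrain_mask <- rep(TRUE, nf)
  if (!config$restrain_hydrogens && !is.null(elements)) {
    restrain_mask <- elements[free] != "H"
  }

  qf <- numeric(nf)
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    R <- numeric(nf)
    if (restraint_a > 0) {
      R[restrain_mask] <- restraint_a /
        sqrt(qf[restrain_mask]^2 + restraint_b^2)
    }
    M <- rbind(cbind(A + diag(R, nf), t(C)),
               cbind(C, matrix(0, nc, nc)))
    rhs <- c(bvec, cvals)
    sol <- tryCatch(solve(M, rhs), error = function(e) {
      stop("singular constrained RESP system: ", conditionMessage(e))
    })
    qnew <- sol[seq_len(nf)]
    delta <- max(abs(qnew - qf))
    qf <- qnew
    if (delta < config$convergence_tol) break
    if (iterations >= config$max_iterations) {
      stop("RESP stage did not converge in ", config$max_iterations,
           " iterations (last max |dq| = ", format(delta), ")")
    }
  }
  q[free] <- qf
  attr(q, "iterations") <- iterations
  q
}

#' Relative RMS error of a charge model against an ESP grid
#'
#' `sqrt(sum((V - V_model)^2) / sum(V^2))`; 0 for a perfect fit, 1 for
#' all-zero charges against a nonzero grid.
#'
#' @param grid an [esp_grid].
#' @param charges fitted charges (e).
#' @return dimensionless relative RMS error.
#' @export
relative_rms_fit <- function(grid, charges) {
  denom <- sum(grid$potentials^2)
  if (denom == 0) stop("reference potentials are all zero")
  vm <- esp_from_point_charges(charges, grid$atom_positions, grid$grid_points)
  sqrt(sum((grid$potentials - vm)^2) / denom)
}

# topology helpers -------------------------------------------------------

# methyl/methylene groups: carbons bonded to >= 2 hydrogens.
# Returns list of list(carbon=, hydrogens=).
.ch_groups <- function(structure) {
  el <- structure$atoms$element
  bonds <- structure$bonds
  groups <- list()
  for (ci in which(el == "C")) {
    nb <- c(bonds[bonds[, 1L] == ci, 2L], bonds[bonds[, 2L] == ci, 1L])
    hs <- nb[el[nb] == "H"]
    if (length(hs) >= 2L) {
      groups[[length(groups) + 1L]] <- list(carbon = ci, hydrogens = sort(hs))
    }
  }
  groups
}

.role_atoms <- function(structure, role) {
  which(!is.na(structure$atoms$role) & structure$atoms$role == role)
}

.flag_atoms <- function(structure, flag, role = NULL) {
  hit <- !is.na(structure$atoms$terminal_flag) &
    structure$atoms$terminal_flag == flag
  if (!is.null(role)) {
    hit <- hit & !is.na(structure$atoms$role) & structure$atoms$role == role
  }
  which(hit)
}

#' Consensus terminal-atom charges
#'
#' The neutral-residue amide/terminal consensus charges of the
#' Cornell-family force fields (ff14SB backbone values), used by the
#' amide-fix scheme.  These are configuration, not fitted results;
#' override them to track a different base force field.  `N_proline`
#' is the Cornell charge for a backbone nitrogen that carries no
#' hydrogen (-0.2548 e).
#'
#' @return named numeric vector with entries `N`, `H`, `C`, `O`,
#'   `N_proline`.
#' @export
consensus_terminal_charges <- function() {
  c(N = -0.4157, H = 0.2719, C = 0.5973, O = -0.5679, N_proline = -0.2548)
}

# constraint schemes ------------------------------------------------------

.methyl_equivalences <- function(structure, cap_hydrogen_equivalence = TRUE) {
  groups <- .ch_groups(structure)
  role <- structure$atoms$role
  eqs <- list()
  for (g in groups) {
    r <- role[g$carbon]
    on_cap <- !is.na(r) && r %in% c("cap_ACE", "cap_NME")
    if (on_cap && !cap_hydrogen_equivalence) next
    if (length(g$hydrogens) >= 2L) {
      eqs[[length(eqs) + 1L]] <- charge_equivalence(g$hydrogens)
    }
  }
  eqs
}

.new_scheme <- function(name, total_charge, constraints) {
  structure(list(name = name, total_charge = total_charge,
                 constraints = constraints),
            class = "constraint_scheme")
}

#' @export
print.constraint_scheme <- function(x, ...) {
  kinds <- vapply(x$constraints, function(c) c$kind, "")
  cat(sprintf("<constraint_scheme> %s: total charge %+d; %d fix, %d group-sum, %d equivalence\n",
              x$name, as.integer(x$total_charge), sum(kinds == "fix"),
              sum(kinds == "group_sum"), sum(kinds == "equivalence")))
  invisible(x)
}

#' Build the free-fit / cap-fix / amide-fix constraint schemes
#'
#' `scheme_free_fit` applies only rotational-equivalence constraints for
#' methyl/methylene hydrogens (honoured in stage 2 of the two-stage fit)
#' plus the total charge.  `scheme_cap_fix` adds a zero group-sum over
#' each capping group (ACE and NME), the minimal constraint set that
#' yields a removable, integer-charge residue.  `scheme_amide_fix`
#' additionally fixes the terminal amide N, H and carbonyl C, O to the
#' consensus charges of the base force field; when the topology has no
#' amide hydrogen (the DsRed/mCherry proline-like amino terminus) the
#' nitrogen is left free and the carbonyl C and O of the adjacent ACE
#' cap are fixed to their force-field values instead.
#'
#' @param structure an annotated [xfp_structure] (roles and terminal
#'   flags set, bonds present).
#' @param total_charge net charge (e) of the full capped system.
#' @param cap_hydrogen_equivalence equivalence cap-methyl hydrogens
#'   within each cap (rotational equivalence never spans groups).
#' @param terminal_reference_charges named vector as returned by
#'   [consensus_terminal_charges()].
#' @return a `constraint_scheme`.
#' @export
scheme_free_fit <- function(structure, total_charge,
                            cap_hydrogen_equivalence = TRUE) {
  eqs <- .methyl_equivalences(structure, cap_hydrogen_equivalence)
  .new_scheme("free_fit", total_charge, eqs)
}

#' @rdname scheme_free_fit
#' @export
scheme_cap_fix <- function(structure, total_charge,
                           cap_hydrogen_equivalence = TRUE) {
  base <- scheme_free_fit(structure, total_charge, cap_hydrogen_equivalence)
  cons <- base$constraints
  for (role in c("cap_ACE", "cap_NME")) {
    atoms <- .role_atoms(structure, role)
    if (!length(atoms)) {
      stop("no atoms annotated with role ", role,
           "; cap-fix scheme needs both capping groups")
    }
    cons[[length(cons) + 1L]] <- charge_group_sum(atoms, 0)
  }
  .new_scheme("cap_fix", total_charge, cons)
}

#' @rdname scheme_free_fit
#' @export
scheme_amide_fix <- function(structure, total_charge,
                             cap_hydrogen_equivalence = TRUE,
                             terminal_reference_charges = consensus_terminal_charges()) {
  base <- scheme_cap_fix(structure, total_charge, cap_hydrogen_equivalence)
  cons <- base$constraints
  ref <- terminal_reference_charges
  need <- function(idx, what) {
    if (length(idx) != 1L) {
      stop("amide-fix scheme needs exactly one ", what,
           " annotation (found ", length(idx), ")")
    }
    idx
  }
  amide_h <- .flag_atoms(structure, "amide_H", role = "chromophore")
  carb_c <- need(.flag_atoms(structure, "carbonyl_C", role = "chromophore"),
                 "chromophore carbonyl_C")
  carb_o <- need(.flag_atoms(structure, "carbonyl_O", role = "chromophore"),
                 "chromophore carbonyl_O")
  cons[[length(cons) + 1L]] <- charge_fix(carb_c, ref[["C"]])
  cons[[length(cons) + 1L]] <- charge_fix(carb_o, ref[["O"]])
  if (length(amide_h)) {
    amide_h <- need(amide_h, "amide_H")
    amide_n <- need(.flag_atoms(structure, "amide_N", role = "chromophore"),
                    "amide_N")
    cons[[length(cons) + 1L]] <- charge_fix(amide_n, ref[["N"]])
    cons[[length(cons) + 1L]] <- charge_fix(amide_h, ref[["H"]])
  } else {
    # proline-like N terminus: leave N free, pin the adjacent ACE C=O
    ace_c <- need(.flag_atoms(structure, "carbonyl_C", role = "cap_ACE"),
                  "ACE carbonyl_C")
    ace_o <- need(.flag_atoms(structure, "carbonyl_O", role = "cap_ACE"),
                  "ACE carbonyl_O")
    cons[[length(cons) + 1L]] <- charge_fix(ace_c, ref[["C"]])
    cons[[length(cons) + 1L]] <- charge_fix(ace_o, ref[["O"]])
  }
  .new_scheme("amide_fix", total_charge, cons)
}

#' Two-stage RESP fit
#'
#' Stage 1 fits all atoms with the weak restraint under the scheme's
#' fix and group-sum constraints.  Stage 2 refits only methyl/methylene
#' carbons and their hydrogens with the stronger restraint and the
#' scheme's hydrogen-equivalence constraints, all other atoms frozen at
#' their stage-1 values.  Topologies without methyl/methylene groups
#' skip stage 2.
#'
#' @param grid an [esp_grid] whose atoms match the structure order.
#' @param structure annotated [xfp_structure] supplying elements, bonds
#'   and roles.
#' @param scheme a `constraint_scheme`.
#' @param config a [resp_config()].
#' @return object of class `resp_result`: `charges`,
#'   `relative_rms_fit`, `stage1_charges`, `iterations_used`
#'   (per stage), `scheme` (name).
#' @export
resp_fit_two_stage <- function(grid, structure, scheme,
                               config = resp_config()) {
  n <- nrow(grid$atom_positions)
  if (n != n_atoms(structure)) {
    stop("grid has ", n, " atoms but structure has ", n_atoms(structure))
  }
  elements <- structure$atoms$element
  kinds <- vapply(scheme$constraints, function(c) c$kind, "")
  stage1_cons <- scheme$constraints[kinds != "equivalence"]
  equivalences <- scheme$constraints[kinds == "equivalence"]

  q1 <- resp_solve_stage(
    grid, total_charge = scheme$total_charge, constraints = stage1_cons,
    restraint_a = config$restraint_a_stage1,
    restraint_b = config$restraint_b, elements = elements, config = config
  )
  it1 <- attr(q1, "iterations")

  groups <- .ch_groups(structure)
  refit <- sort(unique(unlist(lapply(groups, function(g) c(g$carbon, g$hydrogens)))))
  if (!length(refit)) {
    q2 <- q1
    it2 <- 0L
  } else {
    frozen_idx <- setdiff(seq_len(n), refit)
    frozen <- setNames(as.numeric(q1[frozen_idx]), frozen_idx)
    # keep fixed atoms pinned even if they fall inside a refit group
    stage2_cons <- c(
      scheme$constraints[kinds == "fix"],
      Filter(function(e) all(e$atoms %in% refit), equivalences)
    )
    # group sums whose members are partly frozen still bind the free part
    stage2_cons <- c(stage2_cons, scheme$constraints[kinds == "group_sum"])
    q2 <- resp_solve_stage(
      grid, total_charge = scheme$total_charge, constraints = stage2_cons,
      restraint_a = config$restraint_a_stage2,
      restraint_b = config$restraint_b, frozen = frozen,
      elements = elements, config = config
    )
    it2 <- attr(q2, "iterations")
  }
  charges <- as.numeric(q2)
  if (!is.na(scheme$total_charge) &&
      abs(sum(charges) - scheme$total_charge) > 1e-8) {
    stop("fitted charges do not sum to the scheme total (",
         format(sum(charges)), " vs ", scheme$total_charge, ")")
  }
  structure(
    list(charges = charges,
         relative_rms_fit = relative_rms_fit(grid, charges),
         stage1_charges = as.numeric(q1),
         iterations_used = c(stage1 = it1, stage2 = it2),
         scheme = scheme$name),
    class = "resp_result"
  )
}

#' @export
print.resp_result <- function(x, ...) {
  cat(sprintf("<resp_result> scheme %s: %d charges, sum %+.6f, rel RMS fit %.3e\n",
              x$scheme, length(x$charges), sum(x$charges), x$relative_rms_fit))
  invisible(x)
}

# ESP grid file I/O -------------------------------------------------------

#' Read / write ESP grids
#'
#' Two plain-text layouts are supported, both in atomic units (Bohr,
#' hartree/e).  `format = "resp"` is the classic RESP ESP layout: a
#' header line with the atom and point counts, one line of coordinates
#' per atom, then one line per grid point carrying the potential
#' followed by the point coordinates.  `format = "plain"` is one
#' `x y z V` line per point and carries no atom block, so
#' `atom_positions` must be supplied separately when reading.
#'
#' @param x path or text (for reading); an [esp_grid] (for writing).
#' @param format `"resp"` or `"plain"`.
#' @param atom_positions required for `format = "plain"` reads.
#' @param path optional output file for writes.
#' @return [read_esp()] returns an [esp_grid]; [write_esp()] returns the
#'   lines invisibly.
#' @export
read_esp <- function(x, format = c("resp", "plain"), atom_positions = NULL) {
  format <- match.arg(format)
  lines <- .as_lines(x)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  if (format == "resp") {
    hdr <- suppressWarnings(as.integer(toks[[1L]][1:2]))
    if (anyNA(hdr)) stop("bad ESP header line (expected atom and point counts)")
    na <- hdr[1L]; np <- hdr[2L]
    if (length(lines) < 1L + na + np) stop("truncated ESP file")
    atoms <- t(vapply(toks[1L + seq_len(na)], function(t) {
      as.numeric(t[(length(t) - 2L):length(t)])
    }, numeric(3L)))
    pts <- t(vapply(toks[1L + na + seq_len(np)], function(t) {
      as.numeric(t[1:4])
    }, numeric(4L)))
    esp_grid(atoms, pts[, 2:4, drop = FALSE], pts[, 1L])
  } else {
    if (is.null(atom_positions)) {
      stop("plain ESP format carries no atom block; supply atom_positions")
    }
    pts <- t(vapply(toks, function(t) as.numeric(t[1:4]), numeric(4L)))
    esp_grid(atom_positions, pts[, 1:3, drop = FALSE], pts[, 4L])
  }
}

#' @rdname read_esp
#' @export
write_esp <- function(x, path = NULL, format = c("resp", "plain")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "esp_grid"))
  if (format == "resp") {
    out <- c(
      sprintf("%5d%5d", nrow(x$atom_positions), nrow(x$grid_points)),
      sprintf("                %16.7E%16.7E%16.7E",
              x$atom_positions[, 1L], x$atom_positions[, 2L],
              x$atom_positions[, 3L]),
      sprintf("%16.7E%16.7E%16.7E%16.7E", x$potentials,
              x$grid_points[, 1L], x$grid_points[, 2L], x$grid_points[, 3L])
    )
  } else {
    out <- sprintf("%18.10e %18.10e %18.10e %18.10e",
                   x$grid_points[, 1L], x$grid_points[, 2L],
                   x$grid_points[, 3L], x$potentials)
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
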