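# Internal-coordinate measurement and rigid-body superposition.
# Angles are reported in degrees throughout; radians are internal only.

.deg <- 180 / pi

.vnorm <- function(v) sqrt(sum(v * v))

.cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.get_coords <- function(structure, frame) {
  if (inherits(structure, "xfp_structure")) {
    frame_coords(structure, frame)
  } else {
    as.matrix(structure)
  }
}

.check_indices <- function(idx, n) {
  if (anyDuplicated(idx)) stop("atom indices must be distinct")
  if (any(idx < 1L | idx > n)) stop("atom index out of range")
}

#' Bond length between two atoms
#' @param structure an [xfp_structure] (or a coordinate matrix).
#' @param i,j,k,l 1-based atom indices.
#' @param frame frame index.
#' @return length in Angstrom.
#' @export
bond_length <- function(structure, i, j, frame = 1L) {
  co <- .get_coords(structure, frame)
  .check_indices(c(i, j), nrow(co))
  .vnorm(co[j, ] - co[i, ])
}

#' Bond angle i-j-k (vertex at j)
#' @rdname bond_length
#' @return angle in degrees.
#' @export
bond_angle <- function(structure, i, j, k, frame = 1L) {
  co <- .get_coords(structure, frame)
  .check_indices(c(i, j, k), nrow(co))
  u <- co[i, ] - co[j, ]
  v <- co[k, ] - co[j, ]
  nu <- .vnorm(u); nv <- .vnorm(v)
  if (nu < 1e-10 || nv < 1e-10) stop("undefined geometry: coincident atoms")
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) * .deg
}

#' Dihedral angle i-j-k-l about the j-k axis
#'
#' Right-hand sign convention about the j-k axis; result in
#' (-180, 180] degrees with 180 for the trans (anti-planar) arrangement.
#'
#' @rdname bond_length
#' @export
dihedral_angle <- function(structure, i, j, k, l, frame = 1L) {
  co <- .get_coords(structure, frame)
  .check_indices(c(i, j, k, l), nrow(co))
  b1 <- co[j, ] - co[i, ]
  b2 <- co[k, ] - co[j, ]
  b3 <- co[l, ] - co[k, ]
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (.vnorm(n1) < 1e-10 || .vnorm(n2) < 1e-10) {
    stop("undefined geometry: collinear atoms in dihedral")
  }
  m1 <- .cross(n1, b2 / .vnorm(b2))
  # sign matches the convention of the field's trajectory tools:
  # invariant under full index reversal, negated by mirror reflection
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * .deg
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Improper dihedral i-j-k-l with k the central atom
#'
#' Computed as the dihedral of the four positions in order; a planar
#' trigonal center gives 180 degrees (the minimum of every shipped
#' improper term).
#'
#' @rdname bond_length
#' @export
improper_angle <- function(structure, i, j, k, l, frame = 1L) {
  dihedral_angle(structure, i, j, k, l, frame = frame)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mov` onto `ref` over the atom subset.  Reflections are disallowed:
#' the rotation determinant is forced to +1 by sign correction, so
#' molecular chirality is preserved.
#'
#' @param ref,mov structures (or coordinate matrices) sharing atom order.
#' @param subset indices used for the fit (default: all atoms);
#'   at least 3 non-collinear atoms.
#' @param frame_ref,frame_mov frame indices.
#' @return object of class `xfp_superposition`: `rotation` (3x3,
#'   det +1), `translation` (Angstrom), `rmsd` (Angstrom, over the
#'   subset after transform), `atom_subset`.
#' @export
kabsch_superpose <- function(ref, mov, subset = NULL,
                             frame_ref = 1L, frame_mov = 1L) {
  P <- .get_coords(ref, frame_ref)
  Q <- .get_coords(mov, frame_mov)
  if (nrow(P) != nrow(Q)) stop("structures have different atom counts")
  if (is.null(subset)) subset <- seq_len(nrow(P))
  .check_indices(subset, nrow(P))
  if (length(subset) < 3L) stop("superposition needs at least 3 atoms")
  p <- P[subset, , drop = FALSE]
  q <- Q[subset, , drop = FALSE]
  pc <- colMeans(p); qc <- colMeans(q)
  p0 <- sweep(p, 2L, pc); q0 <- sweep(q, 2L, qc)
  if (qr(p0)$rank < 2L || qr(q0)$rank < 2L) {
    stop("degenerate (collinear) atom subset for superposition")
  }
  H <- crossprod(q0, p0)           # 3x3: mov^T ref
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)      # q0 %*% t(R) approximates p0
  moved <- q0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - p0)^2)))
  translation <- pc - as.vector(R %*% qc)
  structure(
    list(rotation = R, translation = translation, rmsd = rmsd,
         atom_subset = subset),
    class = "xfp_superposition"
  )
}

#' @export
print.xfp_superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A over %d atoms\n",
              x$rmsd, length(x$atom_subset)))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param sp an `xfp_superposition`.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(coords %*% t(sp$rotation), 2L, -sp$translation)
}

#' RMSD of two structures after superposition
#'
#' Aligns on `align_subset` and reports the post-alignment RMSD over
#' three atom sets: all atoms, heavy (non-hydrogen) atoms, and the
#' alignment subset itself (published comparisons do not state which
#' set they use, so all three are reported).
#'
#' @param ref,mov [xfp_structure]s sharing atom order.
#' @param align_subset indices used for the alignment (default all).
#' @param frame_ref,frame_mov frame indices.
#' @return named numeric: `all`, `heavy`, `subset`.
#' @export
structure_rmsd <- function(ref, mov, align_subset = NULL,
                           frame_ref = 1L, frame_mov = 1L) {
  sp <- kabsch_superpose(ref, mov, subset = align_subset,
                         frame_ref = frame_ref, frame_mov = frame_mov)
  P <- frame_coords(ref, frame_ref)
  Q <- apply_superposition(sp, frame_coords(mov, frame_mov))
  rms_over <- function(idx) sqrt(mean(rowSums((Q[idx, , drop = FALSE] -
                                               P[idx, , drop = FALSE])^2)))
  heavy <- which(ref$atoms$element != "H")
  c(all = rms_over(seq_len(nrow(P))),
    heavy = if (length(heavy) >= 1L) rms_over(heavy) else NA_real_,
    subset = sp$rmsd)
}

#' Mean unsigned error between two charge sets
#'
#' @param q_a,q_b numeric vectors of equal length (elementary charges).
#' @return mean of absolute differences (e); symmetric in its arguments.
#' @export
#' @examples
#' charge_mue(c(0.1, -0.1), c(0.2, -0.3))  # 0.15
charge_mue <- function(q_a, q_b) {
  if (length(q_a) != length(q_b)) {
    stop("charge vectors have different lengths (", length(q_a), " vs ",
         length(q_b), ")")
  }
  mean(abs(q_a - q_b))
}
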