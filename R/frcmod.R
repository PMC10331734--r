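# FrcmodDocument: a typed AMBER force-field-modification database.
# Sections are kept as data frames in as-shipped order; serialization is
# deterministic so that write -> parse -> write is byte-identical.

.canonical_pair <- function(a, b) {
  fwd <- paste(a, b, sep = "-")
  rev <- paste(b, a, sep = "-")
  ifelse(fwd <= rev, fwd, rev)
}

.canonical_tuple <- function(...) {
  m <- cbind(...)
  fwd <- apply(m, 1L, paste, collapse = "-")
  rev <- apply(m[, rev(seq_len(ncol(m))), drop = FALSE], 1L, paste, collapse = "-")
  ifelse(fwd <= rev, fwd, rev)
}

#' Construct a frcmod document
#'
#' @param title title line of the file.
#' @param mass data frame `atom_type`, `mass`, `polarizability`.
#' @param bonds data frame `a1`, `a2`, `k_r` (kcal/mol/A^2), `r_eq` (A),
#'   `source`.
#' @param angles data frame `a1..a3`, `k_theta` (kcal/mol/rad^2),
#'   `theta_eq` (degrees), `source`.
#' @param torsions data frame `a1..a4`, `paths_divisor`, `half_barrier`
#'   (kcal/mol), `phase` (degrees), `periodicity` (positive; rows sharing
#'   a `group` id form one multi-term torsion), `source`, `group`.
#' @param impropers data frame `a1..a4` (third atom central),
#'   `half_barrier`, `phase`, `periodicity`, `source`.
#' @param nonbonded data frame `atom_type`, `mass`, `polarizability`,
#'   `r_star` (A), `epsilon` (kcal/mol).
#' @return object of class `frcmod`.
#' @export
frcmod_document <- function(title = "frcmod", mass = NULL, bonds = NULL,
                            angles = NULL, torsions = NULL,
                            impropers = NULL, nonbonded = NULL) {
  empty <- function(cols, types) {
    df <- as.data.frame(setNames(lapply(types, function(t) vector(t, 0L)), cols),
                        stringsAsFactors = FALSE)
    df
  }
  if (is.null(mass)) mass <- empty(c("atom_type", "mass", "polarizability"),
                                   c("character", "numeric", "numeric"))
  if (is.null(bonds)) bonds <- empty(c("a1", "a2", "k_r", "r_eq", "source"),
                                     c("character", "character", "numeric",
                                       "numeric", "character"))
  if (is.null(angles)) angles <- empty(
    c("a1", "a2", "a3", "k_theta", "theta_eq", "source"),
    c("character", "character", "character", "numeric", "numeric", "character"))
  if (is.null(torsions)) torsions <- empty(
    c("a1", "a2", "a3", "a4", "paths_divisor", "half_barrier", "phase",
      "periodicity", "source", "group"),
    c("character", "character", "character", "character", "integer",
      "numeric", "numeric", "integer", "character", "integer"))
  if (is.null(impropers)) impropers <- empty(
    c("a1", "a2", "a3", "a4", "half_barrier", "phase", "periodicity", "source"),
    c("character", "character", "character", "character", "numeric",
      "numeric", "integer", "character"))
  if (is.null(nonbonded)) nonbonded <- empty(
    c("atom_type", "mass", "polarizability", "r_star", "epsilon"),
    c("character", "numeric", "numeric", "numeric", "numeric"))
  doc <- structure(
    list(title = title, mass = mass, bonds = bonds, angles = angles,
         torsions = torsions, impropers = impropers, nonbonded = nonbonded),
    class = "frcmod"
  )
  doc
}

#' @export
print.frcmod <- function(x, ...) {
  cat(sprintf(
    "<frcmod> '%s': %d mass, %d bond, %d angle, %d torsion row(s) (%d term group(s)), %d improper, %d nonbonded\n",
    x$title, nrow(x$mass), nrow(x$bonds), nrow(x$angles), nrow(x$torsions),
    length(unique(x$torsions$group)), nrow(x$impropers), nrow(x$nonbonded)))
  invisible(x)
}

#' Validate a frcmod document
#'
#' Checks section invariants: positive force constants, physical
#' equilibrium values, no duplicate keys within a section (bond and
#' angle keys canonicalized under tuple reversal), and that every *new*
#' atom type referenced by a bonded section has mass and nonbonded
#' entries.  Types belonging to the Cornell-family base force fields
#' (which the user is assumed to have loaded) are exempt from the last
#' check.
#'
#' @param doc a `frcmod` document.
#' @param base_types character vector of atom types supplied by the base
#'   force field.
#' @return invisibly `TRUE`; errors name the offending entry.
#' @export
validate_frcmod <- function(doc, base_types = .xfp_base_ff_types) {
  stopifnot(inherits(doc, "frcmod"))
  b <- doc$bonds
  if (nrow(b)) {
    if (any(b$k_r <= 0)) stop("bond force constant must be positive: ",
                              .canonical_pair(b$a1, b$a2)[b$k_r <= 0][1L])
    if (any(b$r_eq <= 0.5 | b$r_eq >= 3.0)) {
      stop("bond r_eq outside (0.5, 3.0) A: ",
           .canonical_pair(b$a1, b$a2)[b$r_eq <= 0.5 | b$r_eq >= 3.0][1L])
    }
    key <- .canonical_pair(b$a1, b$a2)
    if (anyDuplicated(key)) stop("duplicate bond entry: ", key[duplicated(key)][1L])
  }
  a <- doc$angles
  if (nrow(a)) {
    if (any(a$k_theta <= 0)) stop("angle force constant must be positive")
    if (any(a$theta_eq <= 0 | a$theta_eq >= 180)) {
      stop("angle theta_eq outside (0, 180) degrees")
    }
    key <- .canonical_tuple(a$a1, a$a2, a$a3)
    if (anyDuplicated(key)) stop("duplicate angle entry: ", key[duplicated(key)][1L])
  }
  d <- doc$torsions
  if (nrow(d)) {
    if (any(d$paths_divisor < 1L)) stop("torsion paths divisor must be >= 1")
    if (any(abs(d$periodicity) < 1L)) stop("torsion periodicity must be >= 1")
    key <- paste(.canonical_tuple(d$a1, d$a2, d$a3, d$a4), d$periodicity)
    if (anyDuplicated(key)) {
      stop("duplicate torsion term: ", key[duplicated(key)][1L])
    }
  }
  im <- doc$impropers
  if (nrow(im)) {
    key <- paste(im$a3, vapply(seq_len(nrow(im)), function(i) {
      paste(sort(c(im$a1[i], im$a2[i], im$a4[i])), collapse = "-")
    }, ""))
    if (anyDuplicated(key)) {
      stop("duplicate improper entry: ",
           paste(im$a1, im$a2, im$a3, im$a4, sep = "-")[duplicated(key)][1L])
    }
  }
  nb <- doc$nonbonded
  if (nrow(nb)) {
    if (anyDuplicated(nb$atom_type)) {
      stop("duplicate nonbonded entry: ", nb$atom_type[duplicated(nb$atom_type)][1L])
    }
    if (any(nb$r_star <= 0 | nb$epsilon <= 0 | nb$mass <= 0)) {
      stop("nonbonded parameters must be positive")
    }
  }
  if (anyDuplicated(doc$mass$atom_type)) {
    stop("duplicate mass entry: ",
         doc$mass$atom_type[duplicated(doc$mass$atom_type)][1L])
  }
  referenced <- unique(c(b$a1, b$a2, a$a1, a$a2, a$a3,
                         d$a1, d$a2, d$a3, d$a4,
                         im$a1, im$a2, im$a3, im$a4))
  referenced <- setdiff(referenced, c("X", base_types))
  missing_mass <- setdiff(referenced, doc$mass$atom_type)
  if (length(missing_mass)) {
    stop("atom type(s) missing from MASS section: ",
         paste(missing_mass, collapse = ", "))
  }
  missing_nb <- setdiff(referenced, nb$atom_type)
  if (length(missing_nb)) {
    stop("atom type(s) missing from NONBON section: ",
         paste(missing_nb, collapse = ", "))
  }
  invisible(TRUE)
}

#' The shipped xFP chromophore parameter set
#'
#' The complete force-field-modification database needed beyond
#' ff14SB/ff19SB for the seven chromophores: 22 bonds, 56 angles, 40
#' torsion rows (25 logical torsions, the four-component sidechain
#' torsions stored as linked continuation terms), 13 impropers, and 10
#' nonbonded entries.  gaff values follow gaff version 1.81.
#'
#' @return a validated `frcmod` document.
#' @export
#' @examples
#' doc <- builtin_parameter_set()
#' frcmod_lookup(doc, "bond", c("cc", "cd"))$k_r  # 500.9
builtin_parameter_set <- function() {
  nb <- .xfp_nonbonded_table()
  doc <- frcmod_document(
    title = "xFP chromophore parameters (gaff 1.81 + ff14SB analogies)",
    mass = nb[, c("atom_type", "mass", "polarizability")],
    bonds = .xfp_bond_table(),
    angles = .xfp_angle_table(),
    torsions = .xfp_torsion_table(),
    impropers = .xfp_improper_table(),
    nonbonded = nb
  )
  validate_frcmod(doc)
  doc
}

# ---- serialization ----------------------------------------------------

.fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits)

#' Serialize a frcmod document to text
#'
#' Emits sections in the order MASS, BOND, ANGLE, DIHE, IMPROPER, NONBON
#' with AMBER-parseable fixed formatting and deterministic (as-shipped)
#' entry order.  Multi-term torsions are written with negative
#' periodicity on all but their last component (the AMBER continuation
#' convention).  Provenance is carried as a trailing comment per line.
#'
#' @param doc a `frcmod` document (validated before writing).
#' @param path optional output file.
#' @return invisibly, the character vector of lines.
#' @export
write_frcmod <- function(doc, path = NULL) {
  validate_frcmod(doc)
  out <- c(doc$title, "MASS")
  if (nrow(doc$mass)) {
    out <- c(out, sprintf("%-4s %8s %8s", doc$mass$atom_type,
                          .fmt_num(doc$mass$mass, 3L),
                          .fmt_num(doc$mass$polarizability, 3L)))
  }
  out <- c(out, "", "BOND")
  if (nrow(doc$bonds)) {
    out <- c(out, sprintf("%-11s %8s %9s    # %s",
                          paste(doc$bonds$a1, doc$bonds$a2, sep = "-"),
                          .fmt_num(doc$bonds$k_r, 1L),
                          .fmt_num(doc$bonds$r_eq, 4L),
                          doc$bonds$source))
  }
  out <- c(out, "", "ANGLE")
  if (nrow(doc$angles)) {
    out <- c(out, sprintf("%-11s %8s %9s    # %s",
                          paste(doc$angles$a1, doc$angles$a2, doc$angles$a3,
                                sep = "-"),
                          .fmt_num(doc$angles$k_theta, 3L),
                          .fmt_num(doc$angles$theta_eq, 3L),
                          doc$angles$source))
  }
  out <- c(out, "", "DIHE")
  if (nrow(doc$torsions)) {
    d <- doc$torsions
    last_of_group <- !duplicated(d$group, fromLast = TRUE)
    per <- ifelse(last_of_group, d$periodicity, -d$periodicity)
    out <- c(out, sprintf("%-14s %2d %8s %6s %4d    # %s",
                          paste(d$a1, d$a2, d$a3, d$a4, sep = "-"),
                          d$paths_divisor,
                          .fmt_num(d$half_barrier, 3L),
                          .fmt_num(d$phase, 1L),
                          per, d$source))
  }
  out <- c(out, "", "IMPROPER")
  if (nrow(doc$impropers)) {
    im <- doc$impropers
    out <- c(out, sprintf("%-14s %8s %6s %4d    # %s",
                          paste(im$a1, im$a2, im$a3, im$a4, sep = "-"),
                          .fmt_num(im$half_barrier, 1L),
                          .fmt_num(im$phase, 1L),
                          im$periodicity, im$source))
  }
  out <- c(out, "", "NONBON")
  if (nrow(doc$nonbonded)) {
    out <- c(out, sprintf("  %-4s %8s %8s", doc$nonbonded$atom_type,
                          .fmt_num(doc$nonbonded$r_star, 4L),
                          .fmt_num(doc$nonbonded$epsilon, 4L)))
  }
  out <- c(out, "")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Parse frcmod text
#'
#' Accepts the dialect emitted by [write_frcmod()] (tolerant of extra
#' whitespace).  `parse(write(doc))` equals `doc` field-for-field and
#' `write(parse(write(doc)))` is byte-identical to `write(doc)`.
#'
#' @param x path or text.
#' @return a `frcmod` document.
#' @export
parse_frcmod <- function(x) {
  lines <- .as_lines(x)
  if (!length(lines)) stop("empty frcmod input")
  title <- lines[1L]
  sections <- c("MASS", "BOND", "ANGLE", "DIHE", "IMPROPER", "NONBON")
  cur <- NULL
  rows <- setNames(vector("list", length(sections)), sections)
  for (s in sections) rows[[s]] <- list()
  for (i in seq_along(lines)[-1L]) {
    ln <- lines[i]
    t <- trimws(ln)
    if (!nzchar(t)) next
    hdr <- toupper(strsplit(t, "[[:space:]]+")[[1L]][1L])
    if (hdr %in% sections && t == hdr) { cur <- hdr; next }
    if (is.null(cur)) stop("unexpected content before first section at line ", i)
    if (grepl("^[A-Z]+$", t) && !(t %in% sections)) {
      stop("unknown section header '", t, "' at line ", i)
    }
    src <- ""
    if (grepl("#", t, fixed = TRUE)) {
      src <- trimws(sub("^[^#]*#", "", t))
      t <- trimws(sub("#.*$", "", t))
    }
    toks <- strsplit(t, "[[:space:]]+")[[1L]]
    num <- function(s, what) {
      v <- suppressWarnings(as.numeric(s))
      if (anyNA(v)) stop("non-numeric ", what, " field at line ", i, ": '",
                         s[which(is.na(v))[1L]], "'")
      v
    }
    types <- strsplit(toks[1L], "-", fixed = TRUE)[[1L]]
    rows[[cur]][[length(rows[[cur]]) + 1L]] <- switch(
      cur,
      MASS = {
        v <- num(toks[2:3], "mass")
        data.frame(atom_type = toks[1L], mass = v[1L], polarizability = v[2L],
                   stringsAsFactors = FALSE)
      },
      BOND = {
        if (length(types) != 2L) stop("bad bond type field at line ", i)
        v <- num(toks[2:3], "bond")
        data.frame(a1 = types[1L], a2 = types[2L], k_r = v[1L], r_eq = v[2L],
                   source = src, stringsAsFactors = FALSE)
      },
      ANGLE = {
        if (length(types) != 3L) stop("bad angle type field at line ", i)
        v <- num(toks[2:3], "angle")
        data.frame(a1 = types[1L], a2 = types[2L], a3 = types[3L],
                   k_theta = v[1L], theta_eq = v[2L], source = src,
                   stringsAsFactors = FALSE)
      },
      DIHE = {
        if (length(types) != 4L) stop("bad torsion type field at line ", i)
        v <- num(toks[2:5], "torsion")
        data.frame(a1 = types[1L], a2 = types[2L], a3 = types[3L],
                   a4 = types[4L], paths_divisor = as.integer(v[1L]),
                   half_barrier = v[2L], phase = v[3L],
                   periodicity = as.integer(v[4L]), source = src,
                   stringsAsFactors = FALSE)
      },
      IMPROPER = {
        if (length(types) != 4L) stop("bad improper type field at line ", i)
        v <- num(toks[2:4], "improper")
        data.frame(a1 = types[1L], a2 = types[2L], a3 = types[3L],
                   a4 = types[4L], half_barrier = v[1L], phase = v[2L],
                   periodicity = as.integer(v[3L]), source = src,
                   stringsAsFactors = FALSE)
      },
      NONBON = {
        v <- num(toks[2:3], "nonbonded")
        data.frame(atom_type = toks[1L], r_star = v[1L], epsilon = v[2L],
                   stringsAsFactors = FALSE)
      }
    )
  }
  bind <- function(s) if (length(rows[[s]])) do.call(rbind, rows[[s]]) else NULL
  tor <- bind("DIHE")
  if (!is.null(tor)) {
    # reconstruct multi-term groups from the continuation convention
    group <- integer(nrow(tor))
    g <- 0L
    open <- FALSE
    for (i in seq_len(nrow(tor))) {
      if (!open) g <- g + 1L
      group[i] <- g
      open <- tor$periodicity[i] < 0L
    }
    if (open) stop("torsion section ends inside a multi-term continuation")
    tor$periodicity <- abs(tor$periodicity)
    tor$group <- group
  }
  nb <- bind("NONBON")
  mass <- bind("MASS")
  if (!is.null(nb)) {
    # nonbonded entries carry mass/polarizability from the MASS section
    mi <- match(nb$atom_type, if (is.null(mass)) character() else mass$atom_type)
    nb$mass <- if (is.null(mass)) NA_real_ else mass$mass[mi]
    nb$polarizability <- if (is.null(mass)) NA_real_ else mass$polarizability[mi]
    nb <- nb[, c("atom_type", "mass", "polarizability", "r_star", "epsilon")]
  }
  frcmod_document(title = title, mass = mass, bonds = bind("BOND"),
                  angles = bind("ANGLE"), torsions = tor,
                  impropers = bind("IMPROPER"), nonbonded = nb)
}

# ---- lookup -----------------------------------------------------------

#' Look up a parameter entry with AMBER matching semantics
#'
#' Bonds and angles match under tuple reversal.  Torsion matching
#' prefers fully explicit quadruples over wildcard `X-..-X` entries
#' (trying the reversed tuple too) and returns every component of a
#' multi-term torsion in order.  Improper matching keeps the third
#' (central) atom fixed and treats the other three as an unordered set,
#' with `X` matching anything.
#'
#' @param doc a `frcmod` document.
#' @param kind one of `"bond"`, `"angle"`, `"torsion"`, `"improper"`,
#'   `"nonbonded"`, `"mass"`.
#' @param types character vector of atom-type names (length 1, 2, 3 or 4
#'   as appropriate).
#' @return the matching row(s) as a data frame; errors if no match.
#' @export
frcmod_lookup <- function(doc, kind, types) {
  kind <- match.arg(kind, c("bond", "angle", "torsion", "improper",
                            "nonbonded", "mass"))
  tuple_label <- paste(types, collapse = "-")
  notfound <- function() {
    stop("no ", kind, " parameter found for (", tuple_label, ")")
  }
  if (kind == "bond") {
    stopifnot(length(types) == 2L)
    b <- doc$bonds
    hit <- (b$a1 == types[1L] & b$a2 == types[2L]) |
      (b$a1 == types[2L] & b$a2 == types[1L])
    if (!any(hit)) notfound()
    return(b[which(hit)[1L], , drop = FALSE])
  }
  if (kind == "angle") {
    stopifnot(length(types) == 3L)
    a <- doc$angles
    hit <- (a$a1 == types[1L] & a$a2 == types[2L] & a$a3 == types[3L]) |
      (a$a1 == types[3L] & a$a2 == types[2L] & a$a3 == types[1L])
    if (!any(hit)) notfound()
    return(a[which(hit)[1L], , drop = FALSE])
  }
  if (kind == "torsion") {
    stopifnot(length(types) == 4L)
    d <- doc$torsions
    match_dir <- function(row_t, q, wild) {
      all(ifelse(wild & row_t == "X", TRUE, row_t == q))
    }
    find <- function(wild) {
      for (g in unique(d$group)) {
        r <- d[d$group == g, , drop = FALSE]
        t4 <- c(r$a1[1L], r$a2[1L], r$a3[1L], r$a4[1L])
        if (!wild && any(t4 == "X")) next
        if (wild && !any(t4 == "X")) next
        if (match_dir(t4, types, wild) || match_dir(rev(t4), types, wild)) {
          return(r)
        }
      }
      NULL
    }
    hit <- find(wild = FALSE)
    if (is.null(hit)) hit <- find(wild = TRUE)
    if (is.null(hit)) notfound()
    return(hit)
  }
  if (kind == "improper") {
    stopifnot(length(types) == 4L)
    im <- doc$impropers
    q_center <- types[3L]
    q_rest <- types[c(1L, 2L, 4L)]
    for (i in seq_len(nrow(im))) {
      if (im$a3[i] != q_center) next
      stored <- c(im$a1[i], im$a2[i], im$a4[i])
      # match the three outer atoms as a multiset, X matching anything
      rest <- q_rest
      ok <- TRUE
      for (s in stored[stored != "X"]) {
        j <- match(s, rest)
        if (is.na(j)) { ok <- FALSE; break }
        rest <- rest[-j]
      }
      if (ok) return(im[i, , drop = FALSE])
    }
    notfound()
  }
  if (kind == "nonbonded") {
    stopifnot(length(types) == 1L)
    hit <- doc$nonbonded$atom_type == types
    if (!any(hit)) notfound()
    return(doc$nonbonded[which(hit)[1L], , drop = FALSE])
  }
  hit <- doc$mass$atom_type == types[1L]
  if (!any(hit)) notfound()
  doc$mass[which(hit)[1L], , drop = FALSE]
}
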