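# Allowed annotation vocabularies.  Roles mark which fragment an atom belongs
# to during charge fitting; terminal flags mark the backbone atoms that the
# amide-fix charge scheme constrains.
.xfp_roles <- c("chromophore", "cap_ACE", "cap_NME")
.xfp_terminal_flags <- c("none", "amide_N", "amide_H", "carbonyl_C", "carbonyl_O")

.xfp_elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Mn", "Fe", "Co", "Ni", "Cu",
  "Zn", "Se", "Br", "I"
)

#' Build a molecular structure
#'
#' A structure is an ordered set of atoms with one or more coordinate
#' frames (in Angstrom), an optional bond list, and optional per-atom
#' annotations used by the charge-fitting constraint schemes.
#'
#' @param atoms data frame with at least a `name` and `element` column;
#'   optional columns `atom_type`, `charge`, `role`
#'   (`chromophore`, `cap_ACE`, `cap_NME`) and `terminal_flag`
#'   (`none`, `amide_N`, `amide_H`, `carbonyl_C`, `carbonyl_O`).
#' @param frames list of n_atoms x 3 numeric matrices (Angstrom), or a
#'   single matrix for a one-frame structure.
#' @param bonds two-column integer matrix of 1-based atom indices
#'   (may have zero rows).
#' @return an object of class `xfp_structure`.
#' @export
xfp_structure <- function(atoms, frames, bonds = matrix(integer(), 0L, 2L)) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  if (is.null(atoms$name)) stop("atoms must have a 'name' column")
  if (is.null(atoms$element)) stop("atoms must have an 'element' column")
  bad <- setdiff(unique(atoms$element), .xfp_elements)
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  for (col in c("atom_type", "role", "terminal_flag")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_character_
  }
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  ok <- is.na(atoms$role) | atoms$role %in% .xfp_roles
  if (!all(ok)) stop("invalid role: ", paste(unique(atoms$role[!ok]), collapse = ", "))
  ok <- is.na(atoms$terminal_flag) | atoms$terminal_flag %in% .xfp_terminal_flags
  if (!all(ok)) {
    stop("invalid terminal_flag: ",
         paste(unique(atoms$terminal_flag[!ok]), collapse = ", "))
  }
  if (is.matrix(frames)) frames <- list(frames)
  n <- nrow(atoms)
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (!is.matrix(fr) || ncol(fr) != 3L || nrow(fr) != n) {
      stop("frame ", f, " must be a ", n, " x 3 coordinate matrix")
    }
    if (!all(is.finite(fr))) stop("frame ", f, " has non-finite coordinates")
    storage.mode(frames[[f]]) <- "double"
  }
  bonds <- as.matrix(bonds)
  if (length(bonds) && ncol(bonds) != 2L) stop("bonds must have two columns")
  storage.mode(bonds) <- "integer"
  if (length(bonds)) {
    if (any(bonds < 1L | bonds > n)) stop("bond index out of range")
    if (any(bonds[, 1L] == bonds[, 2L])) stop("self-bond not allowed")
  }
  structure(
    list(atoms = atoms, frames = frames, bonds = bonds),
    class = "xfp_structure"
  )
}

#' @export
print.xfp_structure <- function(x, ...) {
  cat(sprintf("<xfp_structure> %d atoms, %d frame(s), %d bond(s)\n",
              nrow(x$atoms), length(x$frames), nrow(x$bonds)))
  invisible(x)
}

#' Number of atoms / frames in a structure
#' @param x an `xfp_structure`.
#' @return integer count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' @rdname n_atoms
#' @export
n_frames <- function(x) length(x$frames)

#' Coordinates of one frame
#' @param x an `xfp_structure`.
#' @param frame frame index (1-based).
#' @return n_atoms x 3 matrix (Angstrom).
#' @export
frame_coords <- function(x, frame = 1L) {
  if (frame < 1L || frame > length(x$frames)) {
    stop("frame ", frame, " out of range (structure has ",
         length(x$frames), " frame(s))")
  }
  x$frames[[frame]]
}

#' Resolve atom names to indices
#'
#' @param x an `xfp_structure`.
#' @param names character vector of atom names.
#' @return integer indices; errors naming the first unresolvable name.
#' @export
atom_index <- function(x, names) {
  idx <- match(names, x$atoms$name)
  if (anyNA(idx)) {
    stop("atom name not found in structure: ", names[which(is.na(idx))[1L]])
  }
  idx
}

# Guess an element symbol from a PDB atom name (fallback when columns 77-78
# are blank).  Strips digits, then tries two-letter and one-letter symbols.
.element_from_name <- function(name) {
  s <- gsub("[^A-Za-z]", "", name)
  if (!nzchar(s)) return(NA_character_)
  two <- paste0(toupper(substr(s, 1L, 1L)), tolower(substr(s, 2L, 2L)))
  if (nchar(s) >= 2L && two %in% .xfp_elements && !(two %in% c("Ca", "Cd", "Nb", "Ne"))) {
    return(two)
  }
  one <- toupper(substr(s, 1L, 1L))
  if (one %in% .xfp_elements) one else NA_character_
}

.as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (length(x) == 1L) {
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(x)
  }
}

#' Read a PDB file or text
#'
#' Parses the ATOM/HETATM/MODEL/ENDMDL/CONECT subset of the PDB format.
#' Each MODEL block becomes one frame (one frame if no MODEL records);
#' CONECT records become bonds.  Coordinates are in Angstrom.
#'
#' @param x path to a PDB file, or PDB text (single string or character
#'   vector of lines).
#' @return an [xfp_structure].
#' @export
read_pdb <- function(x) {
  lines <- .as_lines(x)
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | substr(lines, 1L, 4L) == "ATOM"
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  is_con <- startsWith(lines, "CONECT")

  parse_atom <- function(i) {
    ln <- lines[i]
    if (nchar(ln) < 54L) {
      stop("malformed ATOM/HETATM record at line ", i,
           ": expected at least 54 columns, got ", nchar(ln))
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31L, 38L), substr(ln, 39L, 46L), substr(ln, 47L, 54L)
    )))
    if (anyNA(xyz)) stop("non-numeric coordinate field at line ", i)
    el <- trimws(substr(ln, 77L, 78L))
    name <- trimws(substr(ln, 13L, 16L))
    if (!nzchar(el)) {
      el <- .element_from_name(name)
    } else {
      el <- paste0(toupper(substr(el, 1L, 1L)),
                   tolower(substr(el, 2L, nchar(el))))
    }
    list(
      serial = suppressWarnings(as.integer(substr(ln, 7L, 11L))),
      name = name, resname = trimws(substr(ln, 18L, 20L)),
      element = el, xyz = xyz
    )
  }

  # split atom records into frames by MODEL blocks
  frame_ids <- integer(length(lines))
  cur <- 1L
  seen_model <- FALSE
  for (i in seq_along(lines)) {
    if (is_model[i]) {
      if (seen_model) cur <- cur + 1L
      seen_model <- TRUE
    }
    frame_ids[i] <- cur
  }
  atom_lines <- which(is_atom)
  if (!length(atom_lines)) stop("no ATOM/HETATM records found")
  parsed <- lapply(atom_lines, parse_atom)
  fid <- frame_ids[atom_lines]
  frames_idx <- split(seq_along(parsed), fid)

  first <- frames_idx[[1L]]
  nm <- vapply(parsed[first], function(p) p$name, "")
  el <- vapply(parsed[first], function(p) p$element, "")
  res <- vapply(parsed[first], function(p) p$resname, "")
  serial <- vapply(parsed[first], function(p) p$serial, 1L)
  frames <- lapply(frames_idx, function(ii) {
    if (length(ii) != length(first)) {
      stop("MODEL blocks have differing atom counts (",
           length(first), " vs ", length(ii), ")")
    }
    do.call(rbind, lapply(parsed[ii], function(p) p$xyz))
  })
  names(frames) <- NULL

  bonds <- matrix(integer(), 0L, 2L)
  if (any(is_con)) {
    serial_to_idx <- match(seq_len(max(serial, na.rm = TRUE)), serial)
    pairs <- list()
    for (i in which(is_con)) {
      ln <- lines[i]
      f <- suppressWarnings(as.integer(substr(ln, 7L, 11L)))
      partners <- c(substr(ln, 12L, 16L), substr(ln, 17L, 21L),
                    substr(ln, 22L, 26L), substr(ln, 27L, 31L))
      partners <- suppressWarnings(as.integer(partners))
      partners <- partners[!is.na(partners)]
      ai <- match(f, serial)
      for (p in partners) {
        bi <- match(p, serial)
        if (!is.na(ai) && !is.na(bi)) {
          pairs[[length(pairs) + 1L]] <- sort(c(ai, bi))
        }
      }
    }
    if (length(pairs)) {
      bonds <- unique(do.call(rbind, pairs))
    }
  }

  atoms <- data.frame(
    name = nm, element = el, resname = res,
    stringsAsFactors = FALSE
  )
  xfp_structure(atoms, frames, bonds)
}

#' Write a structure as PDB text
#'
#' Emits HETATM records (MODEL/ENDMDL blocks for multi-frame structures)
#' and CONECT records for any bonds, with coordinates at the format's
#' 3-decimal precision.
#'
#' @param x an [xfp_structure].
#' @param path optional output file; if `NULL` the text is returned.
#' @return invisibly, the character vector of lines.
#' @export
write_pdb <- function(x, path = NULL) {
  resname <- if (!is.null(x$atoms$resname)) x$atoms$resname else "LIG"
  resname <- substr(ifelse(is.na(resname) | !nzchar(resname), "LIG", resname), 1L, 3L)
  out <- character()
  multi <- length(x$frames) > 1L
  for (f in seq_along(x$frames)) {
    if (multi) out <- c(out, sprintf("MODEL     %4d", f))
    co <- x$frames[[f]]
    for (i in seq_len(nrow(co))) {
      name <- x$atoms$name[i]
      # standard PDB name justification: 4-char field starting at col 13
      nf <- if (nchar(name) >= 4L) substr(name, 1L, 4L) else
        formatC(paste0(" ", name), width = -4L)
      if (nchar(name) < 4L) nf <- sprintf(" %-3s", name)
      el <- toupper(x$atoms$element[i])
      out <- c(out, sprintf(
        "HETATM%5d %-4s %3s A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        i, nf, resname[i], co[i, 1L], co[i, 2L], co[i, 3L], el
      ))
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  if (nrow(x$bonds)) {
    for (i in seq_len(nrow(x$bonds))) {
      out <- c(out, sprintf("CONECT%5d%5d", x$bonds[i, 1L], x$bonds[i, 2L]))
    }
  }
  out <- c(out, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Read a (multi-frame) XYZ file or text
#'
#' Standard XYZ layout: an atom count line, a comment line, then one
#' `element x y z` line per atom; repeated blocks are frames and must
#' share the atom count and order.
#'
#' @param x path or text.
#' @return an [xfp_structure] with no bonds.
#' @export
read_xyz <- function(x) {
  lines <- .as_lines(x)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (!length(lines)) stop("empty XYZ input")
  frames <- list()
  elements <- NULL
  i <- 1L
  fidx <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    fidx <- fidx + 1L
    if (is.na(n) || n < 1L) stop("frame ", fidx, ": invalid atom count line ", i)
    if (i + 1L + n > length(lines)) stop("frame ", fidx, ": truncated block")
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "[[:space:]]+")
    el <- vapply(toks, `[[`, "", 1L)
    co <- t(vapply(toks, function(t) {
      v <- suppressWarnings(as.numeric(t[2:4]))
      if (anyNA(v)) stop("frame ", fidx, ": non-numeric coordinates")
      v
    }, numeric(3L)))
    if (is.null(elements)) {
      elements <- el
    } else if (length(el) != length(elements)) {
      stop("frame ", fidx, " has ", length(el), " atoms; expected ",
           length(elements))
    }
    frames[[fidx]] <- co
    i <- i + 2L + n
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  atoms <- data.frame(
    name = paste0(elements, seq_along(elements)),
    element = elements, stringsAsFactors = FALSE
  )
  xfp_structure(atoms, frames)
}

#' Write a structure as multi-frame XYZ text
#' @param x an [xfp_structure].
#' @param path optional output file.
#' @param comment comment line content.
#' @return invisibly, the lines.
#' @export
write_xyz <- function(x, path = NULL, comment = "") {
  out <- character()
  for (f in seq_along(x$frames)) {
    co <- x$frames[[f]]
    out <- c(out, as.character(nrow(co)), comment,
             sprintf("%-2s %12.6f %12.6f %12.6f",
                     x$atoms$element, co[, 1L], co[, 2L], co[, 3L]))
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Read a per-chromophore atom annotation file
#'
#' Plain key-value text, one atom per line:
#' `name atom_type role terminal_flag` (whitespace separated, `#`
#' comments allowed).  Roles and flags use the vocabularies documented
#' in [xfp_structure()].
#'
#' @param x path or text.
#' @return data frame with columns name, atom_type, role, terminal_flag.
#' @export
read_annotations <- function(x) {
  lines <- .as_lines(x)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(toks) != 4L)
  if (length(bad)) stop("annotation line ", bad[1L], " does not have 4 fields")
  out <- data.frame(
    name = vapply(toks, `[[`, "", 1L),
    atom_type = vapply(toks, `[[`, "", 2L),
    role = vapply(toks, `[[`, "", 3L),
    terminal_flag = vapply(toks, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
  ok <- out$role %in% .xfp_roles
  if (!all(ok)) stop("invalid role in annotation file: ", out$role[!ok][1L])
  ok <- out$terminal_flag %in% .xfp_terminal_flags
  if (!all(ok)) {
    stop("invalid terminal_flag in annotation file: ",
         out$terminal_flag[!ok][1L])
  }
  out
}

#' Apply annotations to a structure
#'
#' @param x an [xfp_structure].
#' @param ann annotation data frame from [read_annotations()].
#' @param strict error if any structure atom lacks an annotation.
#' @return the annotated structure.
#' @export
apply_annotations <- function(x, ann, strict = FALSE) {
  idx <- match(x$atoms$name, ann$name)
  if (strict && anyNA(idx)) {
    stop("no annotation for atom(s): ",
         paste(x$atoms$name[is.na(idx)], collapse = ", "))
  }
  hit <- !is.na(idx)
  x$atoms$atom_type[hit] <- ann$atom_type[idx[hit]]
  x$atoms$role[hit] <- ann$role[idx[hit]]
  x$atoms$terminal_flag[hit] <- ann$terminal_flag[idx[hit]]
  x
}

#' Read a plain bond-list file
#'
#' One bond per line as two atom names (whitespace separated); used when
#' a PDB file carries no CONECT records.  Distance-based bond guessing
#' is deliberately not performed: chromophore connectivity is chemically
#' unusual and guessing risks silent errors.
#'
#' @param x path or text.
#' @param structure an [xfp_structure] whose atom names resolve the pairs.
#' @return the structure with bonds set.
#' @export
apply_bond_list <- function(structure, x) {
  lines <- .as_lines(x)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad)) stop("bond-list line ", bad[1L], " does not have 2 fields")
  a <- atom_index(structure, vapply(toks, `[[`, "", 1L))
  b <- atom_index(structure, vapply(toks, `[[`, "", 2L))
  structure$bonds <- cbind(a, b, deparse.level = 0L)
  storage.mode(structure$bonds) <- "integer"
  structure
}
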