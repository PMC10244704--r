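# Element masses (Da). Unknown elements fall back to 12.0 with a warning.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974
)

#' Look up element masses
#'
#' @param element character vector of element symbols.
#' @return numeric vector of masses in Da. Unknown symbols get 12.0 with a
#'   warning.
#' @export
element_mass <- function(element) {
  m <- .element_masses[element]
  unknown <- is.na(m)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(element[unknown]), collapse = ", "),
            "; using default mass 12.0 Da")
    m[unknown] <- 12.0
  }
  unname(m)
}

#' Build an atom table
#'
#' Atoms are stored as a plain data.frame, one row per atom, with element
#' masses resolved from an internal table and a heavy-atom flag
#' (element != "H").
#'
#' @param name atom names (e.g. "NZ", "CD", "CA").
#' @param element element symbols.
#' @param resid residue sequence numbers.
#' @param resname 3-character residue names.
#' @param chain single-character chain identifiers.
#' @param serial atom serial numbers (default 1..n).
#' @return data.frame with columns serial, name, resname, resid, chain,
#'   element, mass, is_heavy.
#' @export
make_atoms <- function(name, element, resid = 1L, resname = "MOL",
                       chain = "A", serial = seq_along(name)) {
  n <- length(name)
  df <- data.frame(
    serial = as.integer(rep_len(serial, n)),
    name = as.character(name),
    resname = as.character(rep_len(resname, n)),
    resid = as.integer(rep_len(resid, n)),
    chain = as.character(rep_len(chain, n)),
    element = as.character(rep_len(element, n)),
    stringsAsFactors = FALSE
  )
  df$mass <- element_mass(df$element)
  df$is_heavy <- df$element != "H"
  df
}

#' Construct a single-frame structure
#'
#' @param atoms atom table from [make_atoms()].
#' @param coords N x 3 numeric matrix of coordinates in Angstrom.
#' @return object of class `md_structure`.
#' @export
md_structure <- function(atoms, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3L)
    stop("coords must be an N x 3 matrix matching the atom table")
  if (!all(is.finite(coords)))
    stop("coordinates must be finite")
  dimnames(coords) <- NULL
  structure(list(atoms = atoms, coords = coords), class = "md_structure")
}

#' Construct a multi-frame trajectory
#'
#' @param atoms shared atom table (topology).
#' @param frames list of N x 3 coordinate matrices (Angstrom), one per frame.
#' @param frame_interval_ps time between recorded frames in ps (default 20).
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(atoms, frames, frame_interval_ps = 20) {
  if (length(frames) < 1L) stop("a trajectory needs at least one frame")
  if (frame_interval_ps <= 0) stop("frame_interval_ps must be > 0")
  n <- nrow(atoms)
  frames <- lapply(seq_along(frames), function(f) {
    m <- as.matrix(frames[[f]])
    storage.mode(m) <- "double"
    if (nrow(m) != n || ncol(m) != 3L)
      stop("frame ", f, " has ", nrow(m), " atoms; topology has ", n)
    if (!all(is.finite(m))) stop("frame ", f, " has non-finite coordinates")
    dimnames(m) <- NULL
    m
  })
  structure(list(atoms = atoms, frames = frames,
                 frame_interval_ps = frame_interval_ps),
            class = "md_trajectory")
}

#' @export
print.md_structure <- function(x, ...) {
  cat("md_structure:", nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", length(x$frames), "frames x", nrow(x$atoms),
      "atoms, dt =", x$frame_interval_ps, "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Extract one frame of a trajectory as a structure
#' @param trajectory an `md_trajectory`.
#' @param i frame index (1-based).
#' @return `md_structure`.
#' @export
get_frame <- function(trajectory, i) {
  md_structure(trajectory$atoms, trajectory$frames[[i]])
}

.atoms_of <- function(x) {
  if (inherits(x, c("md_structure", "md_trajectory"))) x$atoms
  else if (is.data.frame(x)) x
  else stop("expected an md_structure, md_trajectory or atom table")
}

# Element inference from a PDB atom name: first alphabetic character after
# stripping leading digits (handles "NE1" -> N, "1HB" -> H, " CA " -> C).
.element_from_name <- function(name) {
  nm <- sub("^[0-9 ]*", "", name)
  toupper(substr(nm, 1L, 1L))
}

#' Read a (possibly multi-model) PDB file
#'
#' Parses fixed-column ATOM/HETATM records. Each MODEL/ENDMDL block becomes
#' one frame; a file without MODEL records yields a single-frame trajectory.
#' Elements are taken from columns 77-78, falling back to the atom-name
#' convention. Alternate locations other than '' or 'A' are skipped with a
#' warning.
#'
#' @param con file path or connection with PDB text.
#' @param frame_interval_ps frame spacing in ps attached to the result
#'   (default 20, the usual recording stride of the source simulations).
#' @return `md_trajectory`.
#' @export
read_pdb <- function(con, frame_interval_ps = 20) {
  lines <- readLines(con)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(lines, "MODEL")
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id[] <- 1L
  if (!any(is_atom)) stop("no ATOM/HETATM records found")

  altloc <- substr(lines, 17, 17)
  skip <- is_atom & !(altloc %in% c(" ", "", "A"))
  if (any(skip)) {
    warning("skipping ", sum(skip), " record(s) with altloc other than ''/'A'")
    is_atom <- is_atom & !skip
  }

  atom_lines <- which(is_atom)
  groups <- split(atom_lines, model_id[atom_lines])
  n0 <- length(groups[[1]])
  model_names <- names(groups)
  for (g in seq_along(groups)) {
    if (length(groups[[g]]) != n0)
      stop("MODEL ", model_names[g], " has ", length(groups[[g]]),
           " atoms; first frame has ", n0)
  }

  parse_coord <- function(txt, idx) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v))
    if (length(bad))
      stop("unparsable coordinate field at line ", idx[bad[1]])
    v
  }

  first <- lines[groups[[1]]]
  name <- trimws(substr(first, 13, 16))
  resname <- trimws(substr(first, 18, 20))
  chain <- substr(first, 22, 22)
  resid <- suppressWarnings(as.integer(trimws(substr(first, 23, 26))))
  serial <- suppressWarnings(as.integer(trimws(substr(first, 7, 11))))
  element <- trimws(substr(first, 77, 78))
  fallback <- element == "" | is.na(element)
  element[fallback] <- .element_from_name(name[fallback])
  atoms <- make_atoms(name = name, element = element, resid = resid,
                      resname = resname, chain = chain, serial = serial)

  frames <- lapply(groups, function(idx) {
    txt <- lines[idx]
    cbind(parse_coord(substr(txt, 31, 38), idx),
          parse_coord(substr(txt, 39, 46), idx),
          parse_coord(substr(txt, 47, 54), idx))
  })
  names(frames) <- NULL
  md_trajectory(atoms, frames, frame_interval_ps = frame_interval_ps)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL block per frame, coordinates at %8.3f, ENDMDL terminators and a
#' final END record.
#'
#' @param trajectory `md_trajectory` or `md_structure`.
#' @param con file path or connection.
#' @export
write_pdb <- function(trajectory, con) {
  if (inherits(trajectory, "md_structure"))
    trajectory <- md_trajectory(trajectory$atoms, list(trajectory$coords))
  a <- trajectory$atoms
  if (any(vapply(trajectory$frames, function(f) any(abs(f) >= 1e5), logical(1))))
    stop("coordinate magnitude >= 1e5 Angstrom overflows PDB columns")
  # PDB convention: names shorter than 4 characters start in column 14
  nm <- ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name)
  out <- character(0)
  for (f in seq_along(trajectory$frames)) {
    xyz <- trajectory$frames[[f]]
    recs <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    a$serial, nm, a$resname, a$chain, a$resid,
                    xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
    out <- c(out, sprintf("MODEL     %4d", f), recs, "ENDMDL")
  }
  writeLines(c(out, "END"), con)
  invisible(NULL)
}

#' Read a multi-frame XYZ file
#'
#' Standard XYZ blocks: atom-count line, comment line, then `element x y z`
#' rows, repeated per frame.
#'
#' @param con file path or connection.
#' @param frame_interval_ps frame spacing in ps (default 20).
#' @return `md_trajectory`.
#' @export
read_xyz <- function(con, frame_interval_ps = 20) {
  lines <- readLines(con)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list()
  elements <- NULL
  pos <- 1L
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L)
      stop("invalid atom-count line at line ", pos)
    if (pos + 1L + n > length(lines))
      stop("atom-count line at line ", pos, " announces ", n,
           " atoms but the file ends early")
    block <- lines[(pos + 2L):(pos + 1L + n)]
    tok <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(lengths(tok) < 4L)
    if (length(bad))
      stop("malformed XYZ atom line at line ", pos + 1L + bad[1])
    el <- vapply(tok, `[[`, "", 1L)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(is.na(xyz)))
      stop("unparsable coordinates in XYZ block starting at line ", pos)
    if (is.null(elements)) elements <- el
    else if (!identical(elements, el))
      stop("frame ", length(frames) + 1L, " elements differ from first frame")
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
  }
  atoms <- make_atoms(name = elements, element = elements)
  md_trajectory(atoms, frames, frame_interval_ps = frame_interval_ps)
}

#' Write a trajectory as a multi-frame XYZ file
#'
#' @param trajectory `md_trajectory` or `md_structure`.
#' @param con file path or connection.
#' @export
write_xyz <- function(trajectory, con) {
  if (inherits(trajectory, "md_structure"))
    trajectory <- md_trajectory(trajectory$atoms, list(trajectory$coords))
  el <- trajectory$atoms$element
  out <- unlist(lapply(seq_along(trajectory$frames), function(f) {
    xyz <- trajectory$frames[[f]]
    c(as.character(nrow(xyz)), sprintf("frame %d", f),
      sprintf("%-2s %14.6f %14.6f %14.6f", el, xyz[, 1], xyz[, 2], xyz[, 3]))
  }))
  writeLines(out, con)
  invisible(NULL)
}

#' Construct an atom group
#'
#' @param indices strictly increasing 1-based atom indices.
#' @param label descriptive label.
#' @param n_atoms optional topology size for bounds checking.
#' @return object of class `atom_group`.
#' @export
atom_group <- function(indices, label = "", n_atoms = NULL) {
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop("atom group is empty: ", label)
  if (any(diff(indices) <= 0L)) stop("atom group indices must be strictly increasing")
  if (any(indices < 1L)) stop("atom group indices must be >= 1")
  if (!is.null(n_atoms) && any(indices > n_atoms))
    stop("atom group indices exceed topology size")
  structure(list(indices = indices, label = label), class = "atom_group")
}

#' Select atoms with a small selection mini-language
#'
#' The selector is a conjunction of clauses joined by `and`. Supported
#' clauses: `heavy`, `resid 36` (or comma-separated list), `resname LYS`,
#' `name NZ,CD`, `chain A`, `element N`. Selection depends only on the
#' topology, never on coordinates; the result preserves topology order.
#'
#' @param x an `md_structure`, `md_trajectory` or atom table.
#' @param selector selector string, e.g. `"resid 1202 and name N,CA,C"`.
#' @return `atom_group` of matching indices.
#' @export
select_atoms <- function(x, selector) {
  atoms <- .atoms_of(x)
  clauses <- strsplit(trimws(selector), "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(atoms))
  for (cl in clauses) {
    cl <- trimws(cl)
    if (identical(cl, "heavy")) {
      keep <- keep & atoms$is_heavy
      next
    }
    m <- regmatches(cl, regexec("^(resid|resname|name|chain|element)\\s+(\\S+)$", cl))[[1]]
    if (length(m) != 3L)
      stop("cannot parse selector clause '", cl, "' in selector '", selector, "'")
    vals <- strsplit(m[3], ",")[[1]]
    keep <- keep & switch(m[2],
      resid = atoms$resid %in% as.integer(vals),
      resname = atoms$resname %in% vals,
      name = atoms$name %in% vals,
      chain = atoms$chain %in% vals,
      element = atoms$element %in% vals
    )
  }
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("selector '", selector, "' matched no atoms")
  atom_group(idx, label = selector, n_atoms = nrow(atoms))
}

#' Center of mass of an atom group
#'
#' @param coords N x 3 coordinate matrix (one frame).
#' @param group `atom_group` or integer index vector.
#' @param atoms atom table supplying masses (required for mass weighting).
#' @param weighting "mass" (default, element masses) or "geometric"
#'   (unweighted mean).
#' @return length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(coords, group, atoms = NULL,
                           weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  idx <- if (inherits(group, "atom_group")) group$indices else as.integer(group)
  xyz <- coords[idx, , drop = FALSE]
  if (weighting == "geometric") return(colMeans(xyz))
  if (is.null(atoms)) stop("mass weighting needs the atom table")
  w <- atoms$mass[idx]
  as.numeric(crossprod(xyz, w) / sum(w))
}
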