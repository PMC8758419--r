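#' @importFrom stats sd setNames rnorm rpois runif aggregate
#' @importFrom utils read.table write.table head tail
NULL

# ---- Structure -------------------------------------------------------------

ATOM_COLS <- c("serial", "name", "element", "resname", "resno", "chain",
               "x", "y", "z")

#' Construct a Structure from an atom table
#'
#' A `Structure` is a plain atom table (one row per atom) carrying Cartesian
#' coordinates in Angstrom, plus a model id. It is the common currency of all
#' geometric operations in the package.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `x`, `y`, `z` (coordinates in Angstrom).
#' @param model_id Integer model identifier (default 1).
#' @return An object of class `Structure`.
#' @export
new_structure <- function(atoms, model_id = 1L) {
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key))
    stop("duplicate atom identity (chain, resno, name): ",
         key[anyDuplicated(key)][1])
  atoms$resno <- as.integer(atoms$resno)
  atoms$serial <- as.integer(atoms$serial)
  out <- list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
              model_id = as.integer(model_id))
  class(out) <- "Structure"
  out
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, chains %s (model %d)\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")])),
              paste(sort(unique(x$atoms$chain)), collapse = ","),
              x$model_id))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param structure A `Structure`.
#' @return Numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Replace atom coordinates
#' @param structure A `Structure`.
#' @param xyz n x 3 matrix congruent with the atom table.
#' @return The modified `Structure`.
#' @export
set_coords <- function(structure, xyz) {
  stopifnot(nrow(xyz) == nrow(structure$atoms), ncol(xyz) == 3)
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

# Residues in deterministic order (chain, then resno).
residue_table <- function(structure) {
  a <- structure$atoms
  r <- unique(a[, c("chain", "resno", "resname")])
  r[order(r$chain, r$resno), , drop = FALSE]
}

# ---- Selections ------------------------------------------------------------

# Mini-grammar: clauses joined by " and "; each clause is one of
#   chain A [B ...] | resid 200-220 | resid 5,9 | name CA [O ...] |
#   resname HOH [SOL ...]
parse_selection <- function(text) {
  clauses <- strsplit(text, "\\s+and\\s+")[[1]]
  out <- list()
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(toks) < 2) stop("cannot parse selection clause: '", cl, "'")
    key <- toks[1]
    val <- toks[-1]
    if (key == "resid") {
      val <- unlist(strsplit(val, ","))
      nums <- lapply(val, function(v) {
        if (grepl("^-?[0-9]+--?[0-9]+$", v)) {
          m <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
          seq(as.integer(m[2]), as.integer(m[3]))
        } else if (grepl("^-?[0-9]+$", v)) as.integer(v)
        else stop("bad resid token: '", v, "'")
      })
      out$resid <- unique(c(out$resid, unlist(nums)))
    } else if (key %in% c("chain", "name", "resname")) {
      out[[key]] <- unique(c(out[[key]], val))
    } else stop("unknown selection keyword: '", key, "'")
  }
  out
}

#' Select atoms of a Structure
#'
#' @param structure A `Structure`.
#' @param selection Either a selection string in the mini-grammar
#'   `"chain A and resid 200-220 and name CA"` or a named list with any of
#'   `chain`, `resid`, `name`, `resname`.
#' @return Logical vector over the atom rows.
#' @export
atom_mask <- function(structure, selection) {
  a <- structure$atoms
  if (is.character(selection)) selection <- parse_selection(selection)
  keep <- rep(TRUE, nrow(a))
  if (!is.null(selection$chain)) keep <- keep & a$chain %in% selection$chain
  if (!is.null(selection$resid)) keep <- keep & a$resno %in% selection$resid
  if (!is.null(selection$name)) keep <- keep & a$name %in% selection$name
  if (!is.null(selection$resname)) keep <- keep & a$resname %in% selection$resname
  keep
}

#' Subset a Structure by selection
#' @inheritParams atom_mask
#' @return A `Structure` containing the selected atoms.
#' @export
subset_structure <- function(structure, selection) {
  new_structure(structure$atoms[atom_mask(structure, selection), , drop = FALSE],
                structure$model_id)
}

# ---- PDB I/O (bio3d-backed) ------------------------------------------------

pdb_to_structure <- function(pdb, model_id = 1L) {
  at <- pdb$atom
  elem <- trimws(at$elesy)
  noel <- is.na(elem) | elem == ""
  # fall back to the leading letter of the atom name
  elem[noel] <- sub("^[0-9]*([A-Za-z]).*$", "\\1", trimws(at$elety[noel]))
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  new_structure(data.frame(
    serial = at$eleno, name = trimws(at$elety), element = toupper(elem),
    resname = trimws(at$resid), resno = at$resno, chain = chain,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE), model_id)
}

validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records found in PDB input")
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed PDB record at line ", i, ": unreadable coordinates")
  }
  invisible(TRUE)
}

as_pdb_path <- function(source) {
  is_text <- length(source) > 1 || grepl("\n", source) ||
    grepl("^(ATOM|HETATM|MODEL|REMARK|HEADER)", source[1])
  if (is_text) {
    path <- tempfile(fileext = ".pdb")
    writeLines(unlist(strsplit(source, "\n")), path)
    path
  } else {
    if (!file.exists(source)) stop("no such file: ", source)
    source
  }
}

#' Read a structure from PDB text or file
#'
#' @param source Path to a PDB file, or PDB-format text.
#' @param model Which MODEL to return when the file holds several (default 1).
#' @return A `Structure`; atoms in file order, coordinates in Angstrom.
#' @export
read_structure <- function(source, model = 1L) {
  path <- as_pdb_path(source)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty PDB input")
  validate_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model > nmod) stop("model ", model, " requested but file has ", nmod)
  s <- pdb_to_structure(pdb, model_id = as.integer(model))
  if (nmod > 1) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    s <- set_coords(s, xyz)
  }
  s
}

#' Write a Structure as a PDB file
#' @param structure A `Structure`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(coords(structure))),
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain, elesy = a$element)
  invisible(path)
}

# ---- Trajectory ------------------------------------------------------------

#' Construct a Trajectory
#'
#' Ordered coordinate frames over a fixed topology. All frames must hold the
#' same atoms in the same order.
#'
#' @param topology A `Structure` (its coordinates are frame 1's if congruent,
#'   but are not otherwise used).
#' @param frames List of n x 3 coordinate matrices (Angstrom).
#' @param times Optional per-frame times (ns), strictly increasing.
#' @param box Optional orthorhombic box lengths (Angstrom).
#' @return An object of class `Trajectory`.
#' @export
new_trajectory <- function(topology, frames, times = NULL, box = NULL) {
  stopifnot(inherits(topology, "Structure"), is.list(frames),
            length(frames) >= 1)
  nat <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3)
      stop("frame ", i, " is not an n x 3 matrix")
    if (nrow(f) != nat)
      stop("frame ", i, " has ", nrow(f), " atoms; topology has ", nat)
  }
  if (!is.null(times)) {
    if (length(times) != length(frames))
      stop("times length must equal frame count")
    if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  }
  out <- list(topology = topology, frames = frames, times = times, box = box)
  class(out) <- "Trajectory"
  out
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory A `Trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(trajectory) length(trajectory$frames)

#' Read a multi-model PDB as a trajectory
#'
#' @param source Path to a multi-model PDB (or PDB text).
#' @param topology Optional `Structure` to use as topology; must be congruent
#'   with the models in the file.
#' @return A `Trajectory` with one frame per MODEL.
#' @export
read_trajectory <- function(source, topology = NULL) {
  path <- as_pdb_path(source)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty PDB input")
  # bio3d silently recycles on mismatched models; enforce congruence ourselves
  model_starts <- grepl("^MODEL", lines)
  if (any(model_starts)) {
    counts <- integer(0)
    n <- 0L; inside <- FALSE
    for (ln in lines) {
      if (grepl("^MODEL", ln)) { inside <- TRUE; n <- 0L }
      else if (grepl("^ENDMDL", ln)) { inside <- FALSE; counts <- c(counts, n) }
      else if (inside && grepl("^(ATOM|HETATM)", ln)) n <- n + 1L
    }
    if (length(unique(counts)) > 1)
      stop("frame congruence violated: models have atom counts ",
           paste(counts, collapse = ", "))
  }
  validate_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  topo <- pdb_to_structure(pdb)
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
  if (!is.null(topology)) {
    if (nrow(topology$atoms) != nrow(topo$atoms))
      stop("frame congruence violated: topology has ", nrow(topology$atoms),
           " atoms; file models have ", nrow(topo$atoms))
    topo <- topology
  }
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  new_trajectory(topo, frames)
}

#' Write a trajectory as a multi-model PDB
#' @param trajectory A `Trajectory`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(trajectory, path) {
  a <- trajectory$topology$atoms
  xyz <- do.call(rbind, lapply(trajectory$frames, function(f) as.numeric(t(f))))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$resno, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain, elesy = a$element)
  invisible(path)
}

# ---- Profile tables --------------------------------------------------------

#' Construct a ProfileTable
#'
#' A binned 1D profile along the pore (z) axis: a strictly increasing, uniform
#' z grid plus named value columns, with unit metadata.
#'
#' @param z Bin centers, Angstrom; strictly increasing, uniform spacing.
#' @param ... Named numeric columns, each the length of `z`.
#' @param units Named character vector of units, one entry per column
#'   (including `z`).
#' @param reference Reference convention tag (e.g. `"raw"`, `"bulk"`,
#'   `"bilayer_center"`).
#' @param allow_nonuniform Permit a non-uniform z grid (default FALSE).
#' @return An object of class `ProfileTable` (a data.frame with metadata
#'   attributes `units` and `reference`).
#' @export
profile_table <- function(z, ..., units = NULL, reference = "raw",
                          allow_nonuniform = FALSE) {
  cols <- list(...)
  if (!length(cols)) stop("a ProfileTable needs at least one value column")
  if (is.null(names(cols)) || any(names(cols) == ""))
    stop("all value columns must be named")
  if (length(z) < 2) stop("z grid needs at least two bins")
  dz <- diff(z)
  if (any(dz <= 0)) stop("z must be strictly increasing")
  if (!allow_nonuniform &&
      (max(dz) - min(dz)) > 1e-6 * max(abs(dz)))
    stop("z grid is not uniform (pass allow_nonuniform = TRUE to override)")
  for (nm in names(cols))
    if (length(cols[[nm]]) != length(z))
      stop("column '", nm, "' length differs from z")
  df <- data.frame(z = z, cols, stringsAsFactors = FALSE)
  if (is.null(units)) {
    units <- c(z = "Angstrom", setNames(rep("unspecified", length(cols)),
                                        names(cols)))
  }
  if (!"z" %in% names(units)) units <- c(z = "Angstrom", units)
  attr(df, "units") <- units
  attr(df, "reference") <- reference
  class(df) <- c("ProfileTable", "data.frame")
  df
}

#' @export
print.ProfileTable <- function(x, ...) {
  cat(sprintf("ProfileTable: %d bins, columns %s (reference: %s)\n",
              nrow(x), paste(names(x), collapse = ", "),
              attr(x, "reference")))
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Write a ProfileTable to CSV
#'
#' The file carries `#`-prefixed header lines recording the units of every
#' column and the reference convention, so a round trip restores the table
#' exactly (values to 1e-9).
#'
#' @param table A `ProfileTable`.
#' @param path Output path.
#' @param extra_metadata Optional named character vector of extra `# key: value`
#'   header lines.
#' @param allow_nonuniform Write even if the z grid is non-uniform.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(table, path, extra_metadata = NULL,
                          allow_nonuniform = FALSE) {
  stopifnot(inherits(table, "ProfileTable"))
  dz <- diff(table$z)
  if (!allow_nonuniform && (max(dz) - min(dz)) > 1e-6 * max(abs(dz)))
    stop("refusing to write a non-uniform z grid ",
         "(pass allow_nonuniform = TRUE to override)")
  units <- attr(table, "units")
  hdr <- c("# poregate profile",
           paste0("# units: ",
                  paste(names(units), unname(units), sep = "=",
                        collapse = ",")),
           paste0("# reference: ", attr(table, "reference")))
  if (!is.null(extra_metadata))
    hdr <- c(hdr, paste0("# ", names(extra_metadata), ": ",
                         unname(extra_metadata)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ProfileTable from CSV
#' @param path Path written by [write_profile()].
#' @return A `ProfileTable`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^#", lines)]
  unit_line <- grep("^# units:", hdr, value = TRUE)
  if (!length(unit_line))
    stop("profile header missing the '# units:' line: ", path)
  unit_spec <- strsplit(sub("^# units:\\s*", "", unit_line[1]), ",")[[1]]
  kv <- strsplit(unit_spec, "=")
  units <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  ref_line <- grep("^# reference:", hdr, value = TRUE)
  reference <- if (length(ref_line))
    sub("^# reference:\\s*", "", ref_line[1]) else "raw"
  body <- lines[!grepl("^#", lines)]
  df <- read.table(text = body, header = TRUE, sep = ",",
                   stringsAsFactors = FALSE)
  if (!"z" %in% names(df)) stop("profile body lacks a 'z' column: ", path)
  args <- c(list(z = df$z), as.list(df[setdiff(names(df), "z")]),
            list(units = units, reference = reference,
                 allow_nonuniform = TRUE))
  do.call(profile_table, args)
}

# ---- Hydrogen reconstruction ----------------------------------------------

#' Reconstruct backbone amide hydrogens
#'
#' X-ray structures usually lack hydrogens; the hydrogen-bond criterion needs
#' the amide H. For every residue with a preceding residue in the same chain,
#' H is placed 1.01 Angstrom from N along the direction opposed to the
#' bisector of the N-CA and N-C(prev) bonds (the standard planar amide
#' approximation). Existing `H` atoms are kept untouched.
#'
#' @param structure A `Structure`.
#' @return The `Structure` with `H` atoms added (element H, name `"H"`).
#' @export
reconstruct_amide_hydrogens <- function(structure) {
  a <- structure$atoms
  res <- residue_table(structure)
  add <- list()
  serial_next <- max(a$serial) + 1L
  for (i in seq_len(nrow(res))) {
    ch <- res$chain[i]; rn <- res$resno[i]
    if (any(a$chain == ch & a$resno == rn & a$name == "H")) next
    if (res$resname[i] == "PRO") next  # proline has no amide H
    sel_n <- a$chain == ch & a$resno == rn & a$name == "N"
    sel_ca <- a$chain == ch & a$resno == rn & a$name == "CA"
    sel_cp <- a$chain == ch & a$resno == rn - 1L & a$name == "C"
    if (sum(sel_n) != 1 || sum(sel_ca) != 1 || sum(sel_cp) != 1) next
    n <- as.numeric(a[sel_n, c("x", "y", "z")])
    ca <- as.numeric(a[sel_ca, c("x", "y", "z")])
    cp <- as.numeric(a[sel_cp, c("x", "y", "z")])
    dir <- unit(unit(n - ca) + unit(n - cp))
    h <- n + 1.01 * dir
    add[[length(add) + 1]] <- data.frame(
      serial = serial_next, name = "H", element = "H",
      resname = res$resname[i], resno = rn, chain = ch,
      x = h[1], y = h[2], z = h[3], stringsAsFactors = FALSE)
    serial_next <- serial_next + 1L
  }
  if (length(add)) {
    extra <- do.call(rbind, add)
    # keep any non-core columns consistent
    for (nm in setdiff(names(a), names(extra))) extra[[nm]] <- NA
    a <- rbind(a, extra[names(a)])
  }
  new_structure(a, structure$model_id)
}
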