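#' @importFrom stats rnorm runif setNames
#' @importFrom utils head tail
NULL

# Atomic masses (g/mol) for center-of-mass anchors.  Unknown elements
# are a hard error rather than a guessed mass.
ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, K = 39.098, MG = 24.305, ZN = 65.38, FE = 55.845,
  CA = 40.078, MN = 54.938
)
names(ELEMENT_MASSES)[names(ELEMENT_MASSES) == "NA."] <- "NA"

#' Mass of an element symbol
#' @param element character vector of element symbols (e.g. "C", "CL").
#' @return numeric masses in g/mol; unknown symbols are an error.
#' @export
element_mass <- function(element) {
  key <- toupper(element)
  m <- ELEMENT_MASSES[key]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "),
         " - cannot assign a mass", call. = FALSE)
  }
  unname(m)
}

# Derive an element symbol from an atom name.  Names in this package's
# probe templates are simple (C1, HN2, O, N ...); a short list of
# monatomic-ion names covers the common two-letter cases.
.element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  two <- c("CL", "BR", "NA", "MG", "ZN", "FE", "MN")
  vapply(nm, function(x) {
    if (x %in% two) return(x)
    alpha <- gsub("[^A-Z]", "", x)
    if (nchar(alpha) == 0) return("")
    substr(alpha, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

## ---- periodic box ----------------------------------------------------

#' Construct a periodic box
#'
#' Box vectors are the rows of a 3x3 matrix in ångström, following the
#' GROMACS reduced (lower-triangular) convention: v1 = (a, 0, 0),
#' v2 = (bx, by, 0), v3 = (cx, cy, cz).  A box with zero off-diagonal
#' elements is orthorhombic.
#'
#' @param vectors 3x3 numeric matrix (rows are box vectors, Å) or a
#'   length-3 vector of orthorhombic edge lengths.
#' @return An object of class `sim_box`.
#' @export
make_box <- function(vectors) {
  if (is.numeric(vectors) && is.null(dim(vectors)) && length(vectors) == 3) {
    vectors <- diag(vectors)
  }
  stopifnot(is.matrix(vectors), all(dim(vectors) == c(3, 3)),
            all(is.finite(vectors)))
  if (any(diag(vectors) <= 0))
    stop("box diagonal entries must be positive", call. = FALSE)
  upper <- c(vectors[1, 2], vectors[1, 3], vectors[2, 3])
  if (any(abs(upper) > 1e-9))
    stop("box is not in GROMACS reduced form: v1(y), v1(z), v2(z) must be 0",
         call. = FALSE)
  style <- if (all(abs(vectors[lower.tri(vectors)]) < 1e-9))
    "orthorhombic" else "triclinic"
  structure(list(vectors = vectors, style = style), class = "sim_box")
}

#' @export
print.sim_box <- function(x, ...) {
  cat(sprintf("%s box, diag = (%.3f, %.3f, %.3f) A\n", x$style,
              x$vectors[1, 1], x$vectors[2, 2], x$vectors[3, 3]))
  invisible(x)
}

#' Box volume in cubic ångström
#' @param box a [make_box()] object.
#' @export
box_volume <- function(box) {
  stopifnot(inherits(box, "sim_box"))
  abs(det(box$vectors))
}

# CRYST1 cell parameters -> reduced-form vectors (rows), Å and degrees.
.box_from_cell <- function(a, b, c, alpha, beta, gamma) {
  ar <- alpha * pi / 180; br <- beta * pi / 180; gr <- gamma * pi / 180
  v <- matrix(0, 3, 3)
  v[1, 1] <- a
  v[2, 1] <- b * cos(gr)
  v[2, 2] <- b * sin(gr)
  v[3, 1] <- c * cos(br)
  v[3, 2] <- c * (cos(ar) - cos(br) * cos(gr)) / sin(gr)
  v[3, 3] <- sqrt(max(c^2 - v[3, 1]^2 - v[3, 2]^2, 0))
  v[abs(v) < 1e-9] <- 0
  make_box(v)
}

.cell_from_box <- function(box) {
  v <- box$vectors
  a <- sqrt(sum(v[1, ]^2)); b <- sqrt(sum(v[2, ]^2)); c <- sqrt(sum(v[3, ]^2))
  ang <- function(x, y) acos(sum(x * y) / sqrt(sum(x^2) * sum(y^2))) * 180 / pi
  c(a = a, b = b, c = c,
    alpha = ang(v[2, ], v[3, ]), beta = ang(v[1, ], v[3, ]),
    gamma = ang(v[1, ], v[2, ]))
}

## ---- molecular system ------------------------------------------------

# Molecules are maximal runs of atoms sharing (chain, residue id,
# residue name), in file order: the same identity the MD topology uses,
# so 1-based serial indices here match what PLUMED will address.
.group_molecules <- function(atoms) {
  key <- paste(atoms$chain, atoms$resid, atoms$resname, sep = "\r")
  idx <- match(key, unique(key))
  split(seq_len(nrow(atoms)), idx)
}

#' Assemble a molecular system
#'
#' @param atoms data frame with columns `name`, `resname`, `resid`,
#'   `chain` (may be empty strings), `x`, `y`, `z` (Å); `element` and
#'   `serial` are derived if absent.
#' @param box a [make_box()] object.
#' @return Object of class `molecular_system`: the atom table (with
#'   1-based `serial` in file order), the box, and the molecule
#'   partition (list of atom-index vectors keyed by chain/resid/resname).
#' @export
molecular_system <- function(atoms, box) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0, inherits(box, "sim_box"))
  need <- c("name", "resname", "resid", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates", call. = FALSE)
  atoms$serial <- seq_len(nrow(atoms))
  if (is.null(atoms$element)) atoms$element <- .element_from_name(atoms$name)
  mols <- .group_molecules(atoms)
  first <- vapply(mols, `[`, integer(1), 1L)
  mol_tab <- data.frame(
    mol_id = seq_along(mols),
    chain = atoms$chain[first],
    resid = atoms$resid[first],
    resname = atoms$resname[first],
    n_atoms = lengths(mols),
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, box = box, molecules = unname(mols),
                 mol_table = mol_tab),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("molecular_system: %d atoms, %d molecules, %s box\n",
              nrow(x$atoms), length(x$molecules), x$box$style))
  tab <- table(x$mol_table$resname)
  cat("  residues:", paste(sprintf("%s x%d", names(tab), as.integer(tab)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Atom coordinates as an N x 3 matrix (Å)
#' @param system a `molecular_system`.
#' @export
coords <- function(system) {
  as.matrix(system$atoms[, c("x", "y", "z")])
}

## ---- minimum image geometry ------------------------------------------

# Wrap displacement rows (n x 3) to the nearest image.  Orthorhombic
# boxes use the per-axis shortcut; triclinic boxes round in fractional
# space then search the 27 neighbour cells of the reduced lattice
# (required for e.g. GROMACS dodecahedra, where per-axis wrapping is
# not guaranteed minimal).
.min_image_disp <- function(d, box) {
  d <- matrix(d, ncol = 3)
  H <- box$vectors
  if (box$style == "orthorhombic") {
    L <- diag(H)
    for (i in 1:3) d[, i] <- d[, i] - L[i] * round(d[, i] / L[i])
    return(d)
  }
  Hinv <- solve(H)
  f <- d %*% Hinv
  d0 <- (f - round(f)) %*% H
  best <- d0
  best2 <- rowSums(d0^2)
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    if (i == 0 && j == 0 && k == 0) next
    shift <- i * H[1, ] + j * H[2, ] + k * H[3, ]
    cand <- sweep(d0, 2, -shift)  # d0 + shift
    cand2 <- rowSums(cand^2)
    upd <- cand2 < best2
    if (any(upd)) { best[upd, ] <- cand[upd, , drop = FALSE]; best2[upd] <- cand2[upd] }
  }
  best
}

#' Minimum-image distance between two points
#'
#' Shortest distance between `p1` and any periodic image of `p2`.
#' Symmetric in its arguments and invariant under integer lattice
#' translations of either point.
#'
#' @param p1,p2 length-3 numeric vectors (Å).
#' @param box a [make_box()] object.
#' @return scalar distance in Å.
#' @examples
#' b <- make_box(c(40, 40, 40))
#' minimum_image_distance(c(1, 1, 1), c(39, 39, 39), b)  # sqrt(12)
#' @export
minimum_image_distance <- function(p1, p2, box) {
  stopifnot(length(p1) == 3, length(p2) == 3, inherits(box, "sim_box"))
  sqrt(sum(.min_image_disp(rbind(p1 - p2), box)^2))
}

# All minimum-image distances between row sets A (n x 3) and B (m x 3),
# as an n x m matrix.  Used by the RDF, interaction-fraction and toy
# dynamics code; orthorhombic boxes are fully vectorized.
min_image_dist_matrix <- function(A, B, box) {
  A <- matrix(A, ncol = 3); B <- matrix(B, ncol = 3)
  n <- nrow(A); m <- nrow(B)
  H <- box$vectors
  if (box$style == "orthorhombic") {
    L <- diag(H)
    d2 <- matrix(0, n, m)
    for (i in 1:3) {
      dx <- outer(A[, i], B[, i], "-")
      dx <- dx - L[i] * round(dx / L[i])
      d2 <- d2 + dx * dx
    }
    return(sqrt(d2))
  }
  Hinv <- solve(H)
  FA <- A %*% Hinv; FB <- B %*% Hinv
  df <- list(outer(FA[, 1], FB[, 1], "-"),
             outer(FA[, 2], FB[, 2], "-"),
             outer(FA[, 3], FB[, 3], "-"))
  for (i in 1:3) df[[i]] <- df[[i]] - round(df[[i]])
  best2 <- matrix(Inf, n, m)
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    f1 <- df[[1]] + i; f2 <- df[[2]] + j; f3 <- df[[3]] + k
    cx <- f1 * H[1, 1] + f2 * H[2, 1] + f3 * H[3, 1]
    cy <- f2 * H[2, 2] + f3 * H[3, 2]
    cz <- f3 * H[3, 3]
    best2 <- pmin(best2, cx * cx + cy * cy + cz * cz)
  }
  sqrt(best2)
}

# Wrap absolute positions into the primary cell (fractional mod 1).
wrap_positions <- function(pos, box) {
  pos <- matrix(pos, ncol = 3)
  H <- box$vectors
  f <- pos %*% solve(H)
  (f - floor(f)) %*% H
}

## ---- PDB -------------------------------------------------------------

.num <- function(s, line_no, what) {
  x <- suppressWarnings(as.numeric(trimws(s)))
  if (anyNA(x))
    stop(sprintf("parse error at line %d: bad %s field '%s'",
                 line_no, what, s), call. = FALSE)
  x
}

# One PDB model's atom records -> atom data frame.  4-character residue
# names (common for CHARMM-style probe topologies) occupy columns 18-21.
.parse_pdb_atoms <- function(lines, line_nos) {
  n <- length(lines)
  name <- resname <- chain <- alt <- character(n)
  resid <- integer(n)
  xyz <- matrix(0, n, 3)
  elem <- character(n)
  for (i in seq_len(n)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("parse error at line %d: ATOM record shorter than 54 columns",
                   line_nos[i]), call. = FALSE)
    name[i] <- trimws(substr(ln, 13, 16))
    alt[i] <- substr(ln, 17, 17)
    resname[i] <- trimws(substr(ln, 18, 21))
    chain[i] <- trimws(substr(ln, 22, 22))
    resid[i] <- as.integer(.num(substr(ln, 23, 26), line_nos[i], "residue id"))
    xyz[i, 1] <- .num(substr(ln, 31, 38), line_nos[i], "x coordinate")
    xyz[i, 2] <- .num(substr(ln, 39, 46), line_nos[i], "y coordinate")
    xyz[i, 3] <- .num(substr(ln, 47, 54), line_nos[i], "z coordinate")
    e <- if (nchar(ln) >= 78) trimws(substr(ln, 77, 78)) else ""
    elem[i] <- e
  }
  keep <- alt %in% c(" ", "", "A")
  if (!all(keep)) {
    warning(sum(!keep), " atom(s) with alternate location other than 'A' dropped",
            call. = FALSE)
  }
  df <- data.frame(name = name, resname = resname, resid = resid,
                   chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   element = elem, stringsAsFactors = FALSE)
  df <- df[keep, , drop = FALSE]
  noel <- df$element == ""
  df$element[noel] <- .element_from_name(df$name[noel])
  df
}

.read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  cr <- which(rec == "CRYST1")
  if (!length(cr))
    stop("no CRYST1 record: a periodic box is required", call. = FALSE)
  ln <- lines[cr[1]]
  cell <- c(.num(substr(ln, 7, 15), cr[1], "cell a"),
            .num(substr(ln, 16, 24), cr[1], "cell b"),
            .num(substr(ln, 25, 33), cr[1], "cell c"),
            .num(substr(ln, 34, 40), cr[1], "alpha"),
            .num(substr(ln, 41, 47), cr[1], "beta"),
            .num(substr(ln, 48, 54), cr[1], "gamma"))
  box <- .box_from_cell(cell[1], cell[2], cell[3], cell[4], cell[5], cell[6])
  atoms <- .parse_pdb_atoms(lines[is_atom], which(is_atom))
  if (nrow(atoms) == 0) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  molecular_system(atoms, box)
}

.format_pdb_name <- function(name, element) {
  # Standard alignment: names start in column 14 unless 4 characters
  # long or the element symbol has two letters.
  if (nchar(name) >= 4 || nchar(element) == 2) {
    sprintf("%-4s", substr(name, 1, 4))
  } else {
    sprintf(" %-3s", name)
  }
}

.write_pdb <- function(system, path) {
  a <- system$atoms
  cell <- .cell_from_box(system$box)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     cell["a"], cell["b"], cell["c"],
                     cell["alpha"], cell["beta"], cell["gamma"]), con)
  mol_id <- rep(seq_along(system$molecules), lengths(system$molecules))
  mol_id[unlist(system$molecules)] <- mol_id
  for (i in seq_len(nrow(a))) {
    # serials wrap at 100000 (5-column field), per PDB convention
    writeLines(sprintf(
      "ATOM  %5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial[i] %% 100000L,
      .format_pdb_name(a$name[i], a$element[i]),
      a$resname[i],
      ifelse(a$chain[i] == "", " ", a$chain[i]),
      a$resid[i] %% 10000L,
      a$x[i], a$y[i], a$z[i], 1, 0, a$element[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---- GRO -------------------------------------------------------------

.parse_gro_box_line <- function(line, line_no) {
  vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (anyNA(vals) || !(length(vals) %in% c(3, 9)))
    stop(sprintf("parse error at line %d: bad GRO box line", line_no),
         call. = FALSE)
  vals <- vals * ANGSTROM_PER_NM
  v <- matrix(0, 3, 3)
  if (length(vals) == 3) {
    diag(v) <- vals
  } else {
    # order: v1x v2y v3z v1y v1z v2x v2z v3x v3y
    v[1, 1] <- vals[1]; v[2, 2] <- vals[2]; v[3, 3] <- vals[3]
    v[1, 2] <- vals[4]; v[1, 3] <- vals[5]; v[2, 1] <- vals[6]
    v[2, 3] <- vals[7]; v[3, 1] <- vals[8]; v[3, 2] <- vals[9]
  }
  make_box(v)
}

# Parse one GRO frame starting at line `start`; returns atoms/box and
# the index of the next unread line, or NULL when `start` is past EOF.
.parse_gro_frame <- function(lines, start) {
  if (start > length(lines)) return(NULL)
  if (start + 1 > length(lines))
    stop(sprintf("parse error at line %d: truncated GRO header", start),
         call. = FALSE)
  nat <- suppressWarnings(as.integer(trimws(lines[start + 1])))
  if (is.na(nat) || nat <= 0)
    stop(sprintf("parse error at line %d: bad atom count '%s'",
                 start + 1, lines[start + 1]), call. = FALSE)
  last <- start + 1 + nat + 1
  if (last > length(lines))
    stop(sprintf("truncated GRO frame starting at line %d (%d atom lines expected)",
                 start, nat), call. = FALSE)
  idx <- (start + 2):(start + 1 + nat)
  name <- resname <- character(nat); resid <- integer(nat)
  xyz <- matrix(0, nat, 3)
  for (j in seq_len(nat)) {
    ln <- lines[idx[j]]
    if (nchar(ln) < 44)
      stop(sprintf("parse error at line %d: GRO atom line shorter than 44 columns",
                   idx[j]), call. = FALSE)
    resid[j] <- as.integer(.num(substr(ln, 1, 5), idx[j], "residue id"))
    resname[j] <- trimws(substr(ln, 6, 10))
    name[j] <- trimws(substr(ln, 11, 15))
    xyz[j, 1] <- .num(substr(ln, 21, 28), idx[j], "x coordinate")
    xyz[j, 2] <- .num(substr(ln, 29, 36), idx[j], "y coordinate")
    xyz[j, 3] <- .num(substr(ln, 37, 44), idx[j], "z coordinate")
  }
  box <- .parse_gro_box_line(lines[last], last)
  atoms <- data.frame(name = name, resname = resname, resid = resid,
                      chain = "", x = xyz[, 1] * ANGSTROM_PER_NM,
                      y = xyz[, 2] * ANGSTROM_PER_NM,
                      z = xyz[, 3] * ANGSTROM_PER_NM,
                      stringsAsFactors = FALSE)
  list(atoms = atoms, box = box, next_line = last + 1)
}

.read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fr <- .parse_gro_frame(lines, 1)
  if (is.null(fr)) stop("empty GRO file: ", path, call. = FALSE)
  molecular_system(fr$atoms, fr$box)
}

.write_gro_frame <- function(con, atoms, box, title = "written by cosolvr") {
  writeLines(title, con)
  writeLines(sprintf("%5d", nrow(atoms)), con)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     atoms$resid %% 100000L,
                     substr(atoms$resname, 1, 5),
                     substr(atoms$name, 1, 5),
                     atoms$serial %% 100000L,
                     atoms$x / ANGSTROM_PER_NM,
                     atoms$y / ANGSTROM_PER_NM,
                     atoms$z / ANGSTROM_PER_NM), con)
  v <- box$vectors / ANGSTROM_PER_NM
  if (box$style == "orthorhombic") {
    writeLines(sprintf("%10.5f%10.5f%10.5f", v[1, 1], v[2, 2], v[3, 3]), con)
  } else {
    writeLines(paste(sprintf("%10.5f",
      c(v[1, 1], v[2, 2], v[3, 3], v[1, 2], v[1, 3],
        v[2, 1], v[2, 3], v[3, 1], v[3, 2])), collapse = ""), con)
  }
}

.write_gro <- function(system, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_gro_frame(con, system$atoms, system$box)
  invisible(path)
}

## ---- public read/write -----------------------------------------------

.detect_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext == "gro") return("gro")
  stop("cannot auto-detect structure format from extension '", ext,
       "' (use format = 'pdb' or 'gro')", call. = FALSE)
}

#' Read a PDB or GRO structure file
#'
#' Coordinates are stored internally in ångström (GRO files, written in
#' nanometres, are converted at the boundary).  Atoms receive 1-based
#' serial numbers in file order — the indices a PLUMED script will
#' address — and are grouped into molecules by (chain, residue id,
#' residue name).  A periodic box (CRYST1 record or GRO box line) is
#' required.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return A [molecular_system()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(.detect_format(path, format),
         pdb = .read_pdb(path),
         gro = .read_gro(path))
}

#' Write a structure to PDB or GRO
#'
#' Output is fixed-column and re-readable by [read_structure()] (GRO in
#' nm with `%8.3f` coordinates, i.e. 0.001 nm = 0.01 Å precision).
#' Atom/residue names wider than the format's columns are an error —
#' never silently truncated, which would break the round trip.  PDB
#' serials above 99999 wrap modulo 100000 (5-column field).
#'
#' @param system a [molecular_system()].
#' @param path output path.
#' @param format `"auto"`, `"pdb"` or `"gro"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  stopifnot(inherits(system, "molecular_system"))
  if (nrow(system$atoms) == 0) stop("refusing to write a 0-atom system")
  fmt <- .detect_format(path, format)
  wide_name <- if (fmt == "pdb") 4 else 5
  if (any(nchar(system$atoms$name) > wide_name))
    stop("atom name(s) wider than ", wide_name, " characters cannot be written to ",
         toupper(fmt), call. = FALSE)
  if (any(nchar(system$atoms$resname) > 4))
    stop("residue name(s) wider than 4 characters", call. = FALSE)
  switch(fmt, pdb = .write_pdb(system, path), gro = .write_gro(system, path))
}

## ---- frame sources ---------------------------------------------------

#' Build a frame source from in-memory frames
#'
#' A frame source is the trajectory contract used by all analysis
#' functions: a constant atom count, frames indexed from 1 in time
#' order, each with an N x 3 position matrix (Å) and a box.
#'
#' @param positions list of N x 3 matrices (Å).
#' @param boxes a single [make_box()] (constant box) or a list, one per
#'   frame.
#' @return Object of class `frame_source`.
#' @export
frame_source <- function(positions, boxes) {
  stopifnot(is.list(positions), length(positions) > 0)
  n <- nrow(positions[[1]])
  if (!all(vapply(positions, nrow, integer(1)) == n))
    stop("all frames must have the same atom count", call. = FALSE)
  if (inherits(boxes, "sim_box")) boxes <- rep(list(boxes), length(positions))
  stopifnot(length(boxes) == length(positions))
  structure(list(positions = positions, boxes = boxes,
                 n_atoms = n, n_frames = length(positions)),
            class = "frame_source")
}

#' @export
print.frame_source <- function(x, ...) {
  cat(sprintf("frame_source: %d frames x %d atoms\n", x$n_frames, x$n_atoms))
  invisible(x)
}

#' Number of frames in a frame source
#' @param frames a `frame_source`.
#' @export
n_frames <- function(frames) frames$n_frames

#' Positions of one frame
#' @param frames a `frame_source`.
#' @param i 1-based frame index.
#' @return N x 3 matrix (Å).
#' @export
frame_positions <- function(frames, i) {
  if (i < 1 || i > frames$n_frames)
    stop("frame ", i, " not available (", frames$n_frames, " frames",
         if (isTRUE(attr(frames, "truncated"))) "; trajectory was truncated",
         ")", call. = FALSE)
  frames$positions[[i]]
}

#' Box of one frame
#' @inheritParams frame_positions
#' @export
frame_box <- function(frames, i) {
  if (i < 1 || i > frames$n_frames) stop("frame ", i, " not available")
  frames$boxes[[i]]
}

#' Read a multi-frame trajectory (concatenated GRO or multi-MODEL PDB)
#'
#' Frames must all have the atom count of `reference` when one is
#' given.  A truncated final frame raises a warning naming it; the
#' complete earlier frames remain available, and indexing past them is
#' an error.
#'
#' @param path trajectory path.
#' @param reference optional [molecular_system()] to validate atom
#'   counts against.
#' @param format `"auto"`, `"pdb"` or `"gro"`.
#' @return A [frame_source()].
#' @export
read_frames <- function(path, reference = NULL,
                        format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- .detect_format(path, format)
  lines <- readLines(path, warn = FALSE)
  positions <- list(); boxes <- list()
  truncated <- FALSE
  if (fmt == "gro") {
    at <- 1
    repeat {
      fr <- tryCatch(.parse_gro_frame(lines, at), error = function(e) e)
      if (is.null(fr)) break
      if (inherits(fr, "error")) {
        if (length(positions) == 0) stop(fr)
        warning("frame ", length(positions) + 1, " is truncated: ",
                conditionMessage(fr), call. = FALSE)
        truncated <- TRUE
        break
      }
      positions[[length(positions) + 1]] <- as.matrix(fr$atoms[, c("x", "y", "z")])
      boxes[[length(boxes) + 1]] <- fr$box
      at <- fr$next_line
    }
  } else {
    rec <- substr(lines, 1, 6)
    cr <- which(rec == "CRYST1")
    if (!length(cr)) stop("no CRYST1 record in ", path, call. = FALSE)
    ln <- lines[cr[1]]
    box <- .box_from_cell(.num(substr(ln, 7, 15), cr[1], "cell a"),
                          .num(substr(ln, 16, 24), cr[1], "cell b"),
                          .num(substr(ln, 25, 33), cr[1], "cell c"),
                          .num(substr(ln, 34, 40), cr[1], "alpha"),
                          .num(substr(ln, 41, 47), cr[1], "beta"),
                          .num(substr(ln, 48, 54), cr[1], "gamma"))
    starts <- which(rec == "MODEL ")
    blocks <- if (length(starts) == 0) {
      list(which(rec %in% c("ATOM  ", "HETATM")))
    } else {
      ends <- c(starts[-1] - 1, length(lines))
      lapply(seq_along(starts), function(i) {
        rng <- starts[i]:ends[i]
        rng[rec[rng] %in% c("ATOM  ", "HETATM")]
      })
    }
    for (b in blocks) {
      if (!length(b)) next
      res <- tryCatch(.parse_pdb_atoms(lines[b], b), error = function(e) e)
      if (inherits(res, "error")) {
        if (length(positions) == 0) stop(res)
        warning("frame ", length(positions) + 1, " is truncated: ",
                conditionMessage(res), call. = FALSE)
        truncated <- TRUE
        break
      }
      positions[[length(positions) + 1]] <- as.matrix(res[, c("x", "y", "z")])
      boxes[[length(boxes) + 1]] <- box
    }
  }
  if (!length(positions)) stop("no frames read from ", path, call. = FALSE)
  nat <- vapply(positions, nrow, integer(1))
  if (!is.null(reference)) {
    bad <- which(nat != nrow(reference$atoms))
    if (length(bad))
      stop("frame ", bad[1], " has ", nat[bad[1]],
           " atoms; reference has ", nrow(reference$atoms), call. = FALSE)
  } else if (length(unique(nat)) > 1) {
    stop("frame ", which(nat != nat[1])[1], " has a different atom count",
         call. = FALSE)
  }
  fs <- frame_source(positions, boxes)
  attr(fs, "truncated") <- truncated
  fs
}

#' Write a frame source as a concatenated multi-frame GRO file
#'
#' @param frames a [frame_source()].
#' @param system the reference [molecular_system()] supplying atom and
#'   residue names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, system, path) {
  stopifnot(inherits(frames, "frame_source"),
            inherits(system, "molecular_system"),
            frames$n_atoms == nrow(system$atoms))
  con <- file(path, "w")
  on.exit(close(con))
  a <- system$atoms
  for (i in seq_len(frames$n_frames)) {
    a$x <- frames$positions[[i]][, 1]
    a$y <- frames$positions[[i]][, 2]
    a$z <- frames$positions[[i]][, 3]
    .write_gro_frame(con, a, frames$boxes[[i]],
                     title = sprintf("frame %d", i))
  }
  invisible(path)
}
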