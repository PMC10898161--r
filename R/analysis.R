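## Trajectory analyses: radial distribution functions by
## intermolecular-distance binning, interaction-fraction statistics
## (4 Å ionic / 7 Å lipophilic criteria, strict inequality), probe-atom
## density grids, and the grid free energy transform with OpenDX
## export.

GAS_CONSTANT_KCAL <- 1.98720e-3  # kcal mol^-1 K^-1

# Resolve an anchor specification against one frame: an `anchor_set`
# gives per-molecule anchor points; a plain integer vector treats each
# listed atom as its own molecule (used for single-particle systems).
.resolve_points <- function(spec, positions) {
  if (inherits(spec, "anchor_set")) return(anchor_positions(spec, positions))
  if (is.numeric(spec)) return(positions[spec, , drop = FALSE])
  stop("anchor specification must be an anchor_set or atom indices",
       call. = FALSE)
}

#' Subset the frames of a frame source
#' @param frames a [frame_source()].
#' @param idx frame indices to keep.
#' @export
frames_subset <- function(frames, idx) {
  stopifnot(inherits(frames, "frame_source"))
  frame_source(frames$positions[idx], frames$boxes[idx])
}

#' Mean box volume over a trajectory
#'
#' Arithmetic mean of the per-frame box volumes (Å^3) — the
#' denominator entering [expected_density()] for barostatted runs
#' whose box fluctuates.
#'
#' @param frames a [frame_source()].
#' @export
mean_box_volume <- function(frames) {
  mean(vapply(frames$boxes, box_volume, numeric(1)))
}

## ---- radial distribution function ------------------------------------

#' Radial distribution function by intermolecular-distance binning
#'
#' Histograms all minimum-image anchor–anchor distances over the
#' trajectory (excluding self-pairs for a single set) and normalizes by
#' the ideal-gas shell expectation `N_pairs * V_shell(r) / V` per
#' frame, so a uniformly dispersed system gives g(r) = 1.  Aggregation
#' shows up as short-range peaks at the expense of the long-range tail.
#'
#' @param frames a [frame_source()].
#' @param set_a,set_b anchor specifications ([anchor_set()] or atom
#'   index vectors); omit `set_b` for a same-set RDF.
#' @param bin_width bin width, Å (default 0.25).
#' @param r_max histogram range, Å; defaults to (and may not exceed)
#'   half the smallest box dimension.
#' @return Object of class `rdf_result`: bin `edges`, midpoints `r`,
#'   `g`, raw `counts`, and `frames` used.
#' @export
compute_rdf <- function(frames, set_a, set_b = NULL, bin_width = 0.25,
                        r_max = NULL) {
  stopifnot(inherits(frames, "frame_source"), bin_width > 0)
  half_min <- min(vapply(frames$boxes,
                         function(b) min(diag(b$vectors)), numeric(1))) / 2
  if (is.null(r_max)) r_max <- half_min
  if (r_max > half_min + 1e-9)
    stop("r_max = ", r_max, " A exceeds half the minimal box dimension (",
         signif(half_min, 4), " A)", call. = FALSE)
  n_bins <- floor(r_max / bin_width + 1e-9)
  if (n_bins < 1) stop("r_max smaller than one bin", call. = FALSE)
  edges <- (0:n_bins) * bin_width
  shell <- 4 / 3 * pi * diff(edges^3)
  counts <- numeric(n_bins)
  expected <- numeric(n_bins)
  for (fidx in seq_len(frames$n_frames)) {
    pos <- frames$positions[[fidx]]
    box <- frames$boxes[[fidx]]
    A <- .resolve_points(set_a, pos)
    if (is.null(set_b)) {
      dm <- min_image_dist_matrix(A, A, box)
      d <- dm[upper.tri(dm)]
      n_pairs <- nrow(A) * (nrow(A) - 1) / 2
    } else {
      B <- .resolve_points(set_b, pos)
      d <- as.vector(min_image_dist_matrix(A, B, box))
      n_pairs <- nrow(A) * nrow(B)
    }
    if (n_pairs < 1) stop("fewer than one pair of anchors", call. = FALSE)
    bin <- findInterval(d[d < edges[n_bins + 1]], edges,
                        rightmost.closed = FALSE)
    bin <- bin[bin >= 1 & bin <= n_bins]
    counts <- counts + tabulate(bin, nbins = n_bins)
    expected <- expected + n_pairs * shell / box_volume(box)
  }
  structure(list(edges = edges, r = (edges[-1] + edges[-length(edges)]) / 2,
                 g = ifelse(expected > 0, counts / expected, 0),
                 counts = counts, frames = frames$n_frames),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("rdf_result: %d bins to %.2f A over %d frames\n",
              length(x$g), max(x$edges), x$frames))
  invisible(x)
}

## ---- interaction fractions -------------------------------------------

#' Fraction of molecules participating in interactions
#'
#' Per frame, a molecule counts as interacting iff at least one
#' minimum-image distance to another molecule (same-set: any other
#' member; cross-set: any member of the opposite set) is strictly
#' below `cutoff`.  The standard criteria are 7 Å for lipophilic
#' aggregation between hydrophobic probes and 4 Å for
#' acetate–methylammonium ion pairs; distances exactly at the cutoff
#' do not count.  The average pools all frames with equal weight.
#'
#' @param frames a [frame_source()].
#' @param set_a,set_b anchor specifications; omit `set_b` for the
#'   same-set (aggregation) statistic.  Cross-set fractions are taken
#'   over the union of both sets.
#' @param cutoff interaction criterion, Å.
#' @return List: `per_frame` fractions, `average`, `n_molecules`.
#' @export
interaction_fraction <- function(frames, set_a, set_b = NULL, cutoff) {
  stopifnot(inherits(frames, "frame_source"), is.numeric(cutoff), cutoff > 0)
  per_frame <- numeric(frames$n_frames)
  n_mol <- NA_integer_
  for (fidx in seq_len(frames$n_frames)) {
    pos <- frames$positions[[fidx]]
    box <- frames$boxes[[fidx]]
    A <- .resolve_points(set_a, pos)
    if (is.null(set_b)) {
      if (nrow(A) < 2)
        stop("same-set interaction fraction needs at least 2 molecules",
             call. = FALSE)
      dm <- min_image_dist_matrix(A, A, box)
      diag(dm) <- Inf
      inter <- rowSums(dm < cutoff) > 0
      n_mol <- nrow(A)
      per_frame[fidx] <- mean(inter)
    } else {
      B <- .resolve_points(set_b, pos)
      if (nrow(A) < 1 || nrow(B) < 1)
        stop("cross-set interaction fraction needs non-empty sets",
             call. = FALSE)
      dm <- min_image_dist_matrix(A, B, box)
      ia <- rowSums(dm < cutoff) > 0
      ib <- colSums(dm < cutoff) > 0
      n_mol <- nrow(A) + nrow(B)
      per_frame[fidx] <- (sum(ia) + sum(ib)) / n_mol
    }
  }
  list(per_frame = per_frame, average = mean(per_frame), n_molecules = n_mol)
}

## ---- density grids ----------------------------------------------------

# Rigid-body least-squares (Kabsch) fit of P onto Q; returns the
# transform applied to arbitrary coordinates.
.kabsch_transform <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  function(X) sweep(sweep(X, 2, cp) %*% t(R), 2, cq, "+")
}

#' Accumulate a probe-atom density grid over a trajectory
#'
#' Counts the selected atoms into cubic voxels covering the reference
#' (first-frame) box, after wrapping into the primary cell, and
#' normalizes by frames times voxel volume to a number density per
#' voxel.  Optionally performs a rigid-body least-squares fit of
#' selected reference atoms (e.g. protein coordinates) before binning.
#'
#' @param frames a [frame_source()] with an orthorhombic box.
#' @param atoms integer atom indices to bin (e.g. from
#'   [select_group_atoms()]).
#' @param voxel voxel edge, Å (default 1.0).
#' @param label optional group label carried in the result.
#' @param align_idx,align_ref optional: indices of atoms to fit and
#'   their reference N x 3 coordinates; default no alignment.
#' @return Object of class `density_grid`: `origin`, `voxel`, `dims`,
#'   number density array `n`, raw `counts`, `frames`, `label`.
#' @export
accumulate_density <- function(frames, atoms, voxel = 1.0, label = NULL,
                               align_idx = NULL, align_ref = NULL) {
  stopifnot(inherits(frames, "frame_source"), length(atoms) > 0, voxel > 0)
  box <- frames$boxes[[1]]
  if (box$style != "orthorhombic")
    stop("density grids require an orthorhombic box", call. = FALSE)
  L <- diag(box$vectors)
  dims <- pmax(1L, as.integer(ceiling(L / voxel - 1e-9)))
  counts <- numeric(prod(dims))
  do_align <- !is.null(align_idx)
  if (do_align) stopifnot(is.matrix(align_ref),
                          nrow(align_ref) == length(align_idx))
  for (fidx in seq_len(frames$n_frames)) {
    pos <- frames$positions[[fidx]]
    if (do_align) pos <- .kabsch_transform(pos[align_idx, , drop = FALSE],
                                           align_ref)(pos)
    p <- wrap_positions(pos[atoms, , drop = FALSE], box)
    ijk <- floor(p / voxel) + 1
    ijk <- pmax(pmin(ijk, matrix(dims, nrow(p), 3, byrow = TRUE)), 1)
    lin <- ijk[, 1] + dims[1] * (ijk[, 2] - 1) +
      dims[1] * dims[2] * (ijk[, 3] - 1)
    counts <- counts + tabulate(lin, nbins = prod(dims))
  }
  structure(list(origin = c(0, 0, 0), voxel = voxel, dims = dims,
                 n = array(counts / (frames$n_frames * voxel^3), dim = dims),
                 counts = array(counts, dim = dims),
                 frames = frames$n_frames, label = label),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid%s: %d x %d x %d voxels of %.2f A, %d frames\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$dims[1], x$dims[2], x$dims[3], x$voxel, x$frames))
  invisible(x)
}

#' Expected (bulk) number density of an atom group
#'
#' Total group atoms in the box divided by the average box volume over
#' the trajectory — the reference density against which voxel
#' occupancies are compared in the free-energy transform.
#'
#' @param n_atoms total atoms of the group in the box.
#' @param volume average box volume, Å^3 (see [mean_box_volume()]).
#' @return Number density, Å^-3.
#' @export
expected_density <- function(n_atoms, volume) {
  stopifnot(n_atoms >= 0, volume > 0)
  n_atoms / volume
}

#' Grid free energy transform
#'
#' Converts a density grid to voxelwise free energies
#' `-R T ln(n / n_expected)` (kcal/mol; R = 1.98720e-3 kcal/mol/K).
#' Voxels the probes favour come out negative; empty voxels, whose log
#' diverges, are set to `+cap` so the grid stays finite for export.
#'
#' @param grid a [accumulate_density()] result.
#' @param n_expected bulk density from [expected_density()] (> 0).
#' @param temperature reference temperature, K (default 300).
#' @param cap value assigned to empty voxels, kcal/mol (default +3).
#' @return Object of class `gfe_grid` sharing the grid geometry, with
#'   `values` in kcal/mol.
#' @export
grid_free_energy <- function(grid, n_expected, temperature = 300, cap = 3.0) {
  stopifnot(inherits(grid, "density_grid"), n_expected > 0, temperature > 0)
  rt <- GAS_CONSTANT_KCAL * temperature
  vals <- -rt * log(grid$n / n_expected)
  vals[grid$n == 0] <- cap
  structure(list(origin = grid$origin, voxel = grid$voxel, dims = grid$dims,
                 values = vals, temperature = temperature,
                 n_expected = n_expected, cap = cap, label = grid$label),
            class = "gfe_grid")
}

#' @export
print.gfe_grid <- function(x, ...) {
  cat(sprintf("gfe_grid%s: %d x %d x %d voxels, T = %g K, min = %.3f kcal/mol\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$dims[1], x$dims[2], x$dims[3], x$temperature,
              min(x$values)))
  invisible(x)
}

## ---- OpenDX export ----------------------------------------------------

.dx_values <- function(grid) {
  if (inherits(grid, "gfe_grid")) grid$values else grid$n
}

#' Write a grid as an OpenDX scalar field
#'
#' @param grid a `density_grid` or `gfe_grid`.
#' @param path output `.dx` path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, c("density_grid", "gfe_grid")))
  vals <- .dx_values(grid)
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6g %.6g %.6g", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.6g 0 0", grid$voxel),
    sprintf("delta 0 %.6g 0", grid$voxel),
    sprintf("delta 0 0 %.6g", grid$voxel),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  flat <- as.vector(aperm(vals, c(3, 2, 1)))  # z varies fastest
  idx <- seq(1, length(flat), by = 3)
  writeLines(vapply(idx, function(i)
    paste(sprintf("%.8g", flat[i:min(i + 2, length(flat))]), collapse = " "),
    character(1)), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "grid" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field written by [write_dx()]
#'
#' @param path `.dx` file path.
#' @return List with `origin`, `voxel`, `dims` and `values` (array).
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  g1 <- grep("class gridpositions counts", lines, fixed = TRUE, value = TRUE)[1]
  dims <- as.integer(tail(strsplit(trimws(g1), "\\s+")[[1]], 3))
  org <- as.numeric(tail(strsplit(trimws(
    grep("^origin", lines, value = TRUE)[1]), "\\s+")[[1]], 3))
  deltas <- grep("^delta", lines, value = TRUE)
  dvals <- vapply(deltas, function(l)
    as.numeric(tail(strsplit(trimws(l), "\\s+")[[1]], 3)), numeric(3))
  voxel <- max(dvals)
  start <- grep("data follows", lines, fixed = TRUE)[1] + 1
  endmk <- grep("^attribute|^object \"", lines)
  end <- min(endmk[endmk >= start]) - 1
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  stopifnot(length(vals) == prod(dims))
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  list(origin = org, voxel = voxel, dims = dims, values = arr)
}

#' Export a grid with an optional display-threshold mask
#'
#' Writes the grid as OpenDX; when `threshold` is given (the
#' conventional display level is -1.5 kcal/mol for free-energy maps),
#' an additional 0/1 mask grid marking voxels at or below the
#' threshold is written next to it as `<path>_mask.dx`.
#'
#' @param grid a `density_grid` or `gfe_grid`.
#' @param path output `.dx` path.
#' @param threshold optional threshold (same units as the grid values).
#' @return Invisibly, a list of the written path(s).
#' @export
export_grid <- function(grid, path, threshold = NULL) {
  write_dx(grid, path)
  out <- list(grid = path)
  if (!is.null(threshold)) {
    mask <- grid
    mvals <- (.dx_values(grid) <= threshold) * 1
    if (inherits(grid, "gfe_grid")) mask$values <- mvals else mask$n <- mvals
    mpath <- paste0(tools::file_path_sans_ext(path), "_mask.dx")
    write_dx(mask, mpath)
    out$mask <- mpath
  }
  invisible(out)
}
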