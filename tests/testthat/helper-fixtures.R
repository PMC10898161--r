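# Shared fixtures and independent brute-force oracles.  Oracles are
# deliberately naive (nested loops, explicit image enumeration) and
# never call the vectorized implementation paths they check.

# Small mixed probe box: the standard constructed fixture.
fixture_mixed_box <- function(seed = 42, edge = 40,
                              counts = c(BENX = 2, PRPN = 2,
                                         ACET = 1, MAMM = 1)) {
  insert_probes(make_box(rep(edge, 3)), counts, seed = seed)
}

# Single-atom "point probe" template for cheap many-molecule fixtures.
point_template <- function() {
  list(PNT = data.frame(name = "C1", element = "C", x = 0, y = 0, z = 0,
                        stringsAsFactors = FALSE))
}

fixture_point_box <- function(n, edge, seed, min_sep = 0.5) {
  insert_probes(make_box(rep(edge, 3)), c(PNT = n), seed = seed,
                clash_cutoff = min_sep, templates = point_template())
}

# Brute-force minimum-image distance: enumerate 5x5x5 lattice images.
brute_min_image <- function(p1, p2, box) {
  H <- box$vectors
  best <- Inf
  for (i in -2:2) for (j in -2:2) for (k in -2:2) {
    img <- p2 + i * H[1, ] + j * H[2, ] + k * H[3, ]
    best <- min(best, sqrt(sum((p1 - img)^2)))
  }
  best
}

# Random GROMACS-reduced triclinic box.
random_triclinic_box <- function() {
  a <- runif(1, 15, 30); b <- runif(1, 15, 30); c <- runif(1, 15, 30)
  v <- matrix(0, 3, 3)
  v[1, 1] <- a
  v[2, ] <- c(runif(1, -a / 2, a / 2), b, 0)
  v[3, ] <- c(runif(1, -a / 2, a / 2), runif(1, -b / 2, b / 2), c)
  make_box(v)
}

# O(N^2) double-loop interaction-fraction oracle for one frame.
brute_fraction_same <- function(A, box, cutoff) {
  n <- nrow(A)
  inter <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (minimum_image_distance(A[i, ], A[j, ], box) < cutoff) inter[i] <- TRUE
  }
  mean(inter)
}

brute_fraction_cross <- function(A, B, box, cutoff) {
  ia <- logical(nrow(A)); ib <- logical(nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    if (minimum_image_distance(A[i, ], B[j, ], box) < cutoff) {
      ia[i] <- TRUE; ib[j] <- TRUE
    }
  }
  (sum(ia) + sum(ib)) / (nrow(A) + nrow(B))
}

# Frame source with explicit anchor positions (one atom per molecule).
frames_from_points <- function(point_list, box) {
  frame_source(lapply(point_list, function(p) matrix(p, ncol = 3)), box)
}

# A hand-written one-water GRO fixture (nm units).
write_one_water_gro <- function(path) {
  writeLines(c(
    "one water",
    "    1",
    "    1SOL    OW     1   1.000   1.000   1.000",
    "   4.00000   4.00000   4.00000"), path)
  path
}
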