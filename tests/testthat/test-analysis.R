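test_that("a fixed pair at 5 A fills exactly one RDF bin", {
  box <- make_box(c(40, 40, 40))
  pts <- rbind(c(10, 10, 10), c(15, 10, 10))
  fs <- frames_from_points(replicate(10, pts, simplify = FALSE), box)
  rdf <- compute_rdf(fs, 1:2, bin_width = 0.5)
  hit <- which(rdf$counts > 0)
  expect_length(hit, 1)
  expect_true(rdf$edges[hit] <= 5 && 5 < rdf$edges[hit + 1])
  expect_equal(rdf$counts[hit], 10)  # one pair per frame
})

test_that("rdf of a clustered trajectory peaks at short range", {
  sys <- insert_probes(make_box(c(60, 60, 60)), c(BENX = 8), seed = 21)
  sch <- default_scheme()
  aset <- anchor_set(sys, sch$probe_types$benzene)
  cl <- make_synthetic_trajectory(sys, "clustered", n_frames = 10, seed = 22)
  rdf <- compute_rdf(cl, aset, bin_width = 1.0)
  short <- mean(rdf$g[rdf$r < 7])
  long <- mean(rdf$g[rdf$r > 15])
  expect_gt(short, long)
  expect_gt(short, 1)
})

test_that("r_max beyond half the box is rejected", {
  box <- make_box(c(40, 40, 40))
  fs <- frames_from_points(list(rbind(c(1, 1, 1), c(5, 5, 5))), box)
  expect_error(compute_rdf(fs, 1:2, r_max = 25), "half the minimal box")
  expect_silent(compute_rdf(fs, 1:2, r_max = 20))
})

test_that("interaction fractions match hand-built cases and strict cutoffs", {
  box <- make_box(c(100, 100, 100))
  # three molecules mutually within 7 A
  tri <- rbind(c(10, 10, 10), c(14, 10, 10), c(12, 13, 10))
  expect_equal(interaction_fraction(frames_from_points(list(tri), box),
                                    1:3, cutoff = 7)$average, 1.0)
  # two pairs at 6 A separated by 30 A -> 1.0
  quad <- rbind(c(10, 10, 10), c(16, 10, 10), c(46, 10, 10), c(52, 10, 10))
  expect_equal(interaction_fraction(frames_from_points(list(quad), box),
                                    1:4, cutoff = 7)$average, 1.0)
  # isolate one molecule beyond 7 A from all -> 0.75
  iso <- rbind(c(10, 10, 10), c(16, 10, 10), c(22, 10, 10), c(60, 10, 10))
  expect_equal(interaction_fraction(frames_from_points(list(iso), box),
                                    1:4, cutoff = 7)$average, 0.75)
  # boundary: exactly at the cutoff is NOT an interaction (strict "below")
  at4 <- rbind(c(10, 10, 10), c(14, 10, 10))
  expect_equal(interaction_fraction(frames_from_points(list(at4), box),
                                    1, set_b = 2, cutoff = 4)$average, 0)
  just_in <- rbind(c(10, 10, 10), c(13.999, 10, 10))
  expect_equal(interaction_fraction(frames_from_points(list(just_in), box),
                                    1, set_b = 2, cutoff = 4)$average, 1)
  expect_error(interaction_fraction(frames_from_points(list(at4), box),
                                    1, cutoff = 4), "at least 2")
})

test_that("interaction fractions equal the O(N^2) double-loop oracle", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(5:40, 1)
    box <- make_box(runif(3, 25, 50))
    pts <- cbind(runif(n, 0, 25), runif(n, 0, 25), runif(n, 0, 25))
    fs <- frames_from_points(list(pts), box)
    cutoff <- runif(1, 3, 9)
    expect_equal(interaction_fraction(fs, seq_len(n), cutoff = cutoff)$average,
                 brute_fraction_same(pts, box, cutoff))
    k <- sample(2:(n - 2), 1)
    expect_equal(interaction_fraction(fs, seq_len(k), set_b = (k + 1):n,
                                      cutoff = cutoff)$average,
                 brute_fraction_cross(pts[seq_len(k), , drop = FALSE],
                                      pts[(k + 1):n, , drop = FALSE],
                                      box, cutoff))
  }
})

test_that("density grids count atoms into the right voxels", {
  box <- make_box(c(10, 10, 10))
  # single frame, single atom -> one voxel at n = 1/volume
  fs <- frames_from_points(list(rbind(c(2.5, 3.5, 4.5))), box)
  g <- accumulate_density(fs, 1, voxel = 1.0)
  expect_equal(sum(g$counts), 1)
  expect_equal(g$n[3, 4, 5], 1)
  expect_equal(sum(g$n), 1)
  # translation by one box vector leaves the grid unchanged
  fs2 <- frames_from_points(list(rbind(c(2.5, 3.5, 4.5) + c(10, 0, 0))), box)
  g2 <- accumulate_density(fs2, 1, voxel = 1.0)
  expect_equal(g2$n, g$n)
  # totals conserve counts over frames and atoms
  set.seed(24)
  pts <- replicate(7, matrix(runif(30, 0, 10), 10, 3), simplify = FALSE)
  gm <- accumulate_density(frame_source(pts, box), 1:10, voxel = 1.0)
  expect_equal(sum(gm$counts), 7 * 10)
  expect_equal(sum(gm$n) * gm$voxel^3 / 1, 10)  # densities integrate to N
})

test_that("uniform trajectories reproduce the expected density", {
  sys <- fixture_point_box(200, edge = 20, seed = 25)
  fs <- make_synthetic_trajectory(sys, "dispersed", n_frames = 40, seed = 26,
                                  min_sep = 0.3)
  g <- accumulate_density(fs, seq_len(200), voxel = 2.0)
  nexp <- expected_density(200, mean_box_volume(fs))
  expect_equal(nexp, 200 / 20^3)
  expect_equal(mean(g$n), nexp, tolerance = 1e-9)  # exact: counts conserve
  # voxel-level fluctuation: mean within 3 standard errors
  lambda <- nexp * g$voxel^3 * 40
  se <- sqrt(lambda / length(g$n)) / (40 * g$voxel^3)
  expect_lt(abs(mean(g$n) - nexp), 3 * se + 1e-12)
})

test_that("expected density averages fluctuating box volumes", {
  expect_equal(expected_density(100, 1e6), 1e-4)
  boxes <- list(make_box(c(10, 10, 10)), make_box(c(12, 10, 10)))
  fs <- frame_source(list(rbind(c(1, 1, 1)), rbind(c(1, 1, 1))), boxes)
  expect_equal(mean_box_volume(fs), (1000 + 1200) / 2)
})

test_that("grid free energies follow -RT ln(n/n_expected)", {
  box <- make_box(c(4, 4, 4))
  fs <- frames_from_points(list(rbind(c(0.5, 0.5, 0.5))), box)
  g <- accumulate_density(fs, 1, voxel = 1.0)
  # n = n_expected gives 0
  gfe0 <- grid_free_energy(g, n_expected = g$n[1, 1, 1], temperature = 300)
  expect_equal(gfe0$values[1, 1, 1], 0)
  # n = 2 n_expected at 300 K gives -RT ln 2 = -0.413
  gfe2 <- grid_free_energy(g, n_expected = g$n[1, 1, 1] / 2, temperature = 300)
  expect_equal(gfe2$values[1, 1, 1], -0.0019872 * 300 * log(2))
  expect_equal(round(gfe2$values[1, 1, 1], 3), -0.413)
  # empty voxels are capped
  expect_equal(gfe2$values[2, 2, 2], 3.0)
  expect_true(all(is.finite(gfe2$values)))
})

test_that("gfe responds to density rescaling by a uniform shift", {
  sys <- fixture_point_box(50, edge = 15, seed = 27)
  fs <- make_synthetic_trajectory(sys, "dispersed", n_frames = 5, seed = 28,
                                  min_sep = 0.3)
  g <- accumulate_density(fs, seq_len(50), voxel = 3.0)
  nexp <- expected_density(50, mean_box_volume(fs))
  gfe <- grid_free_energy(g, nexp)
  g_scaled <- g; g_scaled$n <- g$n * 2
  gfe_s <- grid_free_energy(g_scaled, nexp)
  occ <- g$n > 0
  rt <- 0.0019872 * 300
  expect_equal(gfe_s$values[occ], gfe$values[occ] - rt * log(2),
               tolerance = 1e-9)
  # monotone decreasing in n
  expect_true(all(gfe$values[occ] > gfe_s$values[occ]))
})

test_that("OpenDX export round-trips and thresholds produce masks", {
  sys <- fixture_point_box(30, edge = 12, seed = 29)
  fs <- make_synthetic_trajectory(sys, "clustered", n_frames = 4, seed = 30)
  g <- accumulate_density(fs, seq_len(30), voxel = 2.0)
  gfe <- grid_free_energy(g, expected_density(30, mean_box_volume(fs)))
  path <- tempfile(fileext = ".dx")
  out <- export_grid(gfe, path, threshold = -1.5)
  back <- read_dx(path)
  expect_equal(back$dims, unname(gfe$dims))
  expect_equal(back$voxel, gfe$voxel)
  expect_lt(max(abs(back$values - gfe$values)), 1e-6)
  mask <- read_dx(out$mask)
  expect_equal(mask$values, (gfe$values <= -1.5) * 1, ignore_attr = TRUE)
  # all-zero grid with a negative threshold gives an empty mask
  zero <- g; zero$n[] <- 0; zero$counts[] <- 0
  out0 <- export_grid(zero, tempfile(fileext = ".dx"), threshold = -1.5)
  expect_equal(sum(read_dx(out0$mask)$values), 0)
})

test_that("rigid-body alignment restores densities of a rotating system", {
  # a fixed cluster observed in a rotating frame: unaligned densities
  # smear, aligned ones reproduce the static grid
  box <- make_box(c(20, 20, 20))
  base <- cbind(runif(12, 8, 12), runif(12, 8, 12), runif(12, 8, 12))
  rot <- function(p, th) {
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    ctr <- c(10, 10, 10)
    sweep(sweep(p, 2, ctr) %*% R, 2, ctr, "+")
  }
  set.seed(31)
  frames <- lapply(seq(0, pi / 2, length.out = 6), function(th) rot(base, th))
  fs <- frame_source(frames, box)
  aligned <- accumulate_density(fs, 1:12, voxel = 2.0,
                                align_idx = 1:12, align_ref = base)
  static <- accumulate_density(frame_source(list(base), box), 1:12, voxel = 2.0)
  expect_equal(aligned$n, static$n, tolerance = 1e-6)
})
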