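test_that("a hand-written GRO file parses with nm-to-angstrom conversion", {
  path <- write_one_water_gro(tempfile(fileext = ".gro"))
  sys <- read_structure(path)
  expect_length(sys$molecules, 1)
  expect_equal(unname(coords(sys)[1, ]), c(10, 10, 10))
  expect_equal(unname(diag(sys$box$vectors)), c(40, 40, 40))
  expect_equal(sys$atoms$resname, "SOL")
  expect_equal(sys$atoms$serial, 1L)
})

test_that("PDB and GRO writing round-trips within format precision", {
  sys <- fixture_mixed_box()
  for (fmt in c("pdb", "gro")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_structure(sys, path)
    back <- read_structure(path)
    # PDB stores 0.001 A, GRO 0.001 nm = 0.01 A
    tol <- if (fmt == "pdb") 5.5e-4 else 5.5e-3
    expect_lt(max(abs(coords(back) - coords(sys))), tol)
    expect_equal(back$atoms$name, sys$atoms$name)
    expect_equal(back$atoms$resname, sys$atoms$resname)
    expect_equal(back$box$vectors, sys$box$vectors, tolerance = 1e-3)
    expect_length(back$molecules, length(sys$molecules))
  }
})

test_that("residues with the same name but different ids become distinct molecules", {
  lines <- c(
    "CRYST1   40.000   40.000   40.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  C1  BENX    1       1.000   1.000   1.000  1.00  0.00           C",
    "ATOM      2  C2  BENX    1       2.000   1.000   1.000  1.00  0.00           C",
    "ATOM      3  C1  BENX    2      10.000  10.000  10.000  1.00  0.00           C",
    "ATOM      4  C2  BENX    2      11.000  10.000  10.000  1.00  0.00           C",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  sys <- read_structure(path)
  expect_length(sys$molecules, 2)
  expect_true(all(sys$mol_table$resname == "BENX"))
  # partition property: molecule sizes sum to the atom count
  expect_equal(sum(lengths(sys$molecules)), nrow(sys$atoms))
})

test_that("malformed lines and missing boxes are informative errors", {
  bad <- tempfile(fileext = ".gro")
  writeLines(c("t", "    1",
               "    1SOL    OW     1   1.000   xxx     1.000",
               "   4.0   4.0   4.0"), bad)
  expect_error(read_structure(bad), "line 3")
  nobox <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1  BENX    1       1.000   1.000   1.000  1.00  0.00           C",
    "END"), nobox)
  expect_error(read_structure(nobox), "CRYST1")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("zero-atom systems and oversized names are refused at write time", {
  expect_error(molecular_system(data.frame(), make_box(c(10, 10, 10))))
  sys <- fixture_mixed_box()
  sys$atoms$name[1] <- "CALPHA"
  expect_error(write_structure(sys, tempfile(fileext = ".pdb")), "wider")
})

test_that("alternate locations other than A are dropped with a warning", {
  lines <- c(
    "CRYST1   40.000   40.000   40.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  C1 ABENX    1       1.000   1.000   1.000  1.00  0.00           C",
    "ATOM      2  C1 BBENX    1       1.500   1.000   1.000  1.00  0.00           C",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  expect_warning(sys <- read_structure(path), "alternate location")
  expect_equal(nrow(sys$atoms), 1)
})

test_that("minimum image distance matches hand arithmetic and is symmetric", {
  b <- make_box(c(40, 40, 40))
  expect_equal(minimum_image_distance(c(1, 1, 1), c(39, 39, 39), b), sqrt(12))
  expect_equal(minimum_image_distance(c(5, 5, 5), c(5, 5, 5), b), 0)
  p1 <- c(3, 17, 38); p2 <- c(39, 2, 4)
  expect_equal(minimum_image_distance(p1, p2, b),
               minimum_image_distance(p2, p1, b))
  # invariance under integer lattice translations of either point
  shift <- c(2, -1, 3) %*% b$vectors
  expect_equal(minimum_image_distance(p1 + shift, p2, b),
               minimum_image_distance(p1, p2, b))
})

test_that("triclinic minimum image agrees with brute-force image enumeration", {
  set.seed(101)
  for (case in 1:1000) {
    box <- random_triclinic_box()
    span <- colSums(abs(box$vectors))
    p1 <- runif(3) * span; p2 <- runif(3) * span
    expect_equal(minimum_image_distance(p1, p2, box),
                 brute_min_image(p1, p2, box), tolerance = 1e-10)
  }
  # the vectorized distance matrix agrees with the scalar path
  box <- random_triclinic_box()
  A <- matrix(runif(15) * 20, 5, 3); B <- matrix(runif(9) * 20, 3, 3)
  dm <- cosolvr:::min_image_dist_matrix(A, B, box)
  for (i in 1:5) for (j in 1:3)
    expect_equal(dm[i, j], brute_min_image(A[i, ], B[j, ], box),
                 tolerance = 1e-10)
})

test_that("trajectory reading yields frames in order and flags truncation", {
  sys <- fixture_mixed_box()
  fs <- make_synthetic_trajectory(sys, "dispersed", n_frames = 3, seed = 5)
  path <- tempfile(fileext = ".gro")
  write_frames(fs, sys, path)
  back <- read_frames(path, reference = sys)
  expect_equal(n_frames(back), 3)
  for (i in 1:3)
    expect_lt(max(abs(frame_positions(back, i) - fs$positions[[i]])), 5.5e-3)

  # single-frame file equals read_structure
  single <- tempfile(fileext = ".gro")
  write_structure(sys, single)
  one <- read_frames(single)
  expect_equal(n_frames(one), 1)
  expect_equal(frame_positions(one, 1), unname(coords(read_structure(single))),
               ignore_attr = TRUE)

  # truncate the last frame: earlier frames usable, access past them errors
  lines <- readLines(path)
  writeLines(head(lines, length(lines) - 5), path)
  expect_warning(tr <- read_frames(path, reference = sys), "truncated")
  expect_equal(n_frames(tr), 2)
  expect_silent(frame_positions(tr, 2))
  expect_error(frame_positions(tr, 3), "truncated")

  # atom-count mismatch names the frame
  expect_error(suppressWarnings(read_frames(path, reference = read_structure(
    write_one_water_gro(tempfile(fileext = ".gro"))))), "frame 1")
})

test_that("the PDB parser agrees with bio3d on a shared fixture", {
  skip_if_not_installed("bio3d")
  sys <- fixture_mixed_box()
  path <- tempfile(fileext = ".pdb")
  write_structure(sys, path)
  ref <- bio3d::read.pdb(path)
  expect_equal(unname(coords(read_structure(path))),
               unname(cbind(ref$atom$x, ref$atom$y, ref$atom$z)))
  expect_equal(read_structure(path)$atoms$resname, ref$atom$resid)
})
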