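test_that("COM anchors are emitted per molecule, central atoms are not", {
  sys <- insert_probes(make_box(c(40, 40, 40)), c(BENX = 2), seed = 6)
  sch <- default_scheme()
  anchors <- emit_anchors(sys, sch)
  expect_length(anchors, 2)
  for (a in anchors) {
    expect_equal(a$action, "COM")
    expect_length(a$keywords$ATOMS, 12)
  }
  expect_equal(vapply(anchors, `[[`, character(1), "label"),
               c("benzene_1_com", "benzene_2_com"))
  # a central-atom-only scheme emits no COM directives
  sch2 <- restraint_scheme(
    list(probe_type("propane", "PRPN", anchor_central_atom("C2"))),
    list(pair_rule("propane", "propane")))
  sys2 <- insert_probes(make_box(c(40, 40, 40)), c(PRPN = 3), seed = 6)
  expect_length(emit_anchors(sys2, sch2), 0)
})

test_that("the mixed fixture yields the directive counts pair combinatorics imply", {
  sys <- fixture_mixed_box()  # 2 BENX, 2 PRPN, 1 ACET, 1 MAMM
  script <- generate_plumed(sys, default_scheme())
  acts <- vapply(script$directives, `[[`, character(1), "action")
  expect_equal(sum(acts == "COM"), 2)          # benzene COMs only
  # C(2,2) + 2*2 + C(2,2) hydrophobic + 1*1 ionic
  expect_equal(sum(acts == "DISTANCE"), 1 + 4 + 1 + 1)
  expect_equal(sum(acts == "LOWER_WALLS"), 4)
  expect_equal(sum(acts == "PRINT"), 1)
  # wall ARG arity equals that rule's pair count
  walls <- script$directives[acts == "LOWER_WALLS"]
  arity <- vapply(walls, function(w) length(w$keywords$ARG), integer(1))
  expect_equal(sort(arity), c(1, 1, 1, 4))
  pr <- script$directives[[which(acts == "PRINT")]]
  expect_length(pr$keywords$ARG, 4)
  expect_equal(pr$keywords$STRIDE, 500)
})

test_that("rules without enough molecules are skipped with a warning", {
  sys <- insert_probes(make_box(c(40, 40, 40)), c(BENX = 2, PRPN = 1), seed = 8)
  w <- capture_warnings(script <- generate_plumed(sys, default_scheme()))
  expect_true(any(grepl("propane_propane", w)))
  expect_true(any(grepl("acetate_methylammonium", w)))
  acts <- vapply(script$directives, `[[`, character(1), "action")
  # benzene-benzene (1) + propane-benzene (2); propane-propane and the
  # ionic rule are skipped
  expect_equal(sum(acts == "DISTANCE"), 3)
  expect_equal(sum(acts == "LOWER_WALLS"), 2)
})

test_that("rendering is byte-identical across runs and grammar-valid", {
  sys <- fixture_mixed_box()
  t1 <- render_plumed(generate_plumed(sys, default_scheme()))
  t2 <- render_plumed(generate_plumed(sys, default_scheme()))
  expect_identical(t1, t2)
  expect_true(validate_plumed(t1))
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(t1, f1); writeLines(t2, f2)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
})

test_that("wall directives carry engine units: production vs soft", {
  sys <- fixture_mixed_box()
  prod <- render_plumed(generate_plumed(sys, default_scheme(), mode = "production"))
  soft <- render_plumed(generate_plumed(sys, default_scheme(), mode = "soft"))
  wall_prod <- grep("LOWER_WALLS", prod, value = TRUE)[1]
  expect_match(wall_prod, "AT=0.8 ")
  expect_match(wall_prod, "KAPPA=20000 ")
  expect_match(wall_prod, "EXP=4 ")
  expect_match(wall_prod, "EPS=1 ")
  expect_match(wall_prod, "OFFSET=0$")
  wall_soft <- grep("LOWER_WALLS", soft, value = TRUE)[1]
  expect_match(wall_soft, "KAPPA=10 ")
  expect_match(wall_soft, "EXP=2 ")
  # soft mode changes only the KAPPA/EXP fields of wall lines
  norm <- function(x) gsub("KAPPA=[0-9,.]+|EXP=[0-9,]+", "",
                           x[!grepl("^#", x)])
  expect_identical(norm(prod), norm(soft))
})

test_that("mixed-anchor distances reference one serial and one COM label", {
  sys <- insert_probes(make_box(c(40, 40, 40)), c(BENX = 1, PRPN = 1), seed = 9)
  sch <- restraint_scheme(
    list(probe_type("benzene", "BENX", anchor_com()),
         probe_type("propane", "PRPN", anchor_central_atom("C2"))),
    list(pair_rule("propane", "benzene")))
  script <- generate_plumed(sys, sch)
  acts <- vapply(script$directives, `[[`, character(1), "action")
  d <- script$directives[[which(acts == "DISTANCE")[1]]]
  refs <- d$keywords$ATOMS
  expect_length(refs, 2)
  expect_match(refs[1], "^[0-9]+$")          # propane central carbon serial
  expect_match(refs[2], "^benzene_1_com$")   # benzene COM label
  # the serial is the PRPN C2 atom in file order
  idx <- which(sys$atoms$resname == "PRPN" & sys$atoms$name == "C2")
  expect_equal(as.integer(refs[1]), idx)
})

test_that("the grammar checker enforces definition-before-use and label uniqueness", {
  good <- c("a_com: COM ATOMS=1,2,3",
            "d_1: DISTANCE ATOMS=a_com,4",
            "w: LOWER_WALLS ARG=d_1 AT=0.8 KAPPA=20000 EXP=4 EPS=1.0 OFFSET=0",
            "p: PRINT ARG=w.bias STRIDE=500 FILE=bias.dat")
  expect_true(validate_plumed(good))
  expect_error(validate_plumed(good[c(2, 1, 3, 4)]), "undefined label")
  expect_error(validate_plumed(c(good, "a_com: COM ATOMS=9")), "duplicate")
  expect_error(validate_plumed("not a directive"), "does not match")
})

test_that("the emitted wall parameters reproduce the analytic bias model", {
  sys <- fixture_mixed_box()
  for (mode in c("production", "soft")) {
    script <- generate_plumed(sys, default_scheme(), mode = mode)
    acts <- vapply(script$directives, `[[`, character(1), "action")
    wd <- script$directives[[which(acts == "LOWER_WALLS")[1]]]
    # parse the rendered text back, reconstruct the wall, compare energies
    parsed <- parse_plumed(.render <- cosolvr:::.render_directive(wd))
    w_script <- wall_params_from_directive(parsed[[1]])
    w_ref <- if (mode == "production") production_wall() else soft_wall()
    x_nm <- seq(0, 1.2, by = 0.05)
    expect_equal(wall_energy(x_nm, w_script), wall_energy(x_nm, w_ref),
                 tolerance = 1e-9)
    # and against the kcal/angstrom statement of the same wall
    w_kcal <- convert_wall_params(w_script, "kcal/mol", "angstrom")
    expect_equal(wall_energy(x_nm * 10, w_kcal) * 4.184,
                 wall_energy(x_nm, w_ref), tolerance = 1e-9)
  }
})
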