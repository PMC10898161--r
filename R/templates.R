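# Idealized single-copy geometries (Å) for the seven cosolvent probes.
# Bond lengths/angles are standard textbook values; these templates seed
# the synthetic box builder and define the atom names that anchors and
# density groups resolve against.  Residue codes are package defaults —
# force-field topologies vary, so schemes may override them.

.template_df <- function(name, element, xyz) {
  data.frame(name = name, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

.benzene_template <- function() {
  ang <- (0:5) * pi / 3
  c_xyz <- cbind(1.396 * cos(ang), 1.396 * sin(ang), 0)
  h_xyz <- cbind(2.485 * cos(ang), 2.485 * sin(ang), 0)
  .template_df(c(paste0("C", 1:6), paste0("H", 1:6)),
               c(rep("C", 6), rep("H", 6)),
               rbind(c_xyz, h_xyz))
}

.propane_template <- function() {
  xyz <- rbind(
    c(0.855, 1.268, 0),            # C1
    c(1.920, 1.220, 0), c(0.530, 1.850, 0.880), c(0.530, 1.850, -0.880),
    c(0, 0, 0),                    # C2 (central carbon, anchor)
    c(-0.630, 0, 0.890), c(-0.630, 0, -0.890),
    c(0.855, -1.268, 0),           # C3
    c(1.920, -1.220, 0), c(0.530, -1.850, 0.880), c(0.530, -1.850, -0.880)
  )
  .template_df(c("C1", "H11", "H12", "H13", "C2", "H21", "H22",
                 "C3", "H31", "H32", "H33"),
               c("C", "H", "H", "H", "C", "H", "H", "C", "H", "H", "H"),
               xyz)
}

.methanol_template <- function() {
  xyz <- rbind(
    c(0, 0, 0),                    # C
    c(1.430, 0, 0),                # O
    c(1.760, 0.840, 0),            # HO (donor hydrogen)
    c(-0.360, -1.030, 0), c(-0.360, 0.510, 0.890), c(-0.360, 0.510, -0.890)
  )
  .template_df(c("C", "O", "HO", "H1", "H2", "H3"),
               c("C", "O", "H", "H", "H", "H"), xyz)
}

.formamide_template <- function() {
  xyz <- rbind(
    c(0, 0, 0),                    # C (anchor)
    c(0.610, 1.056, 0),            # O (acceptor)
    c(0.675, -1.169, 0),           # N
    c(-1.090, 0, 0),               # HC
    c(1.675, -1.250, 0),           # HN1 (donor)
    c(0.100, -1.990, 0)            # HN2 (donor)
  )
  .template_df(c("C", "O", "N", "HC", "HN1", "HN2"),
               c("C", "O", "N", "H", "H", "H"), xyz)
}

.acetaldehyde_template <- function() {
  xyz <- rbind(
    c(0.755, -1.307, 0),           # C1 methyl
    c(1.830, -1.200, 0), c(0.450, -1.890, 0.880), c(0.450, -1.890, -0.880),
    c(0, 0, 0),                    # C2 carbonyl (anchor)
    c(-1.090, 0, 0),               # HC
    c(0.610, 1.056, 0)             # O (acceptor)
  )
  .template_df(c("C1", "H11", "H12", "H13", "C2", "HC", "O"),
               c("C", "H", "H", "H", "C", "H", "O"), xyz)
}

.acetate_template <- function() {
  xyz <- rbind(
    c(-1.520, 0, 0),               # C1 methyl
    c(-1.900, -1.010, 0), c(-1.900, 0.510, 0.880), c(-1.900, 0.510, -0.880),
    c(0, 0, 0),                    # C2 carboxylic carbon (anchor)
    c(0.630, 1.090, 0),            # O1
    c(0.630, -1.090, 0)            # O2
  )
  .template_df(c("C1", "H1", "H2", "H3", "C2", "O1", "O2"),
               c("C", "H", "H", "H", "C", "O", "O"), xyz)
}

.methylammonium_template <- function() {
  xyz <- rbind(
    c(0, 0, 0),                    # C
    c(-0.360, -1.030, 0), c(-0.360, 0.510, 0.890), c(-0.360, 0.510, -0.890),
    c(1.500, 0, 0),                # N (anchor)
    c(1.860, 0.960, 0), c(1.860, -0.480, 0.830), c(1.860, -0.480, -0.830)
  )
  .template_df(c("C", "H1", "H2", "H3", "N", "HN1", "HN2", "HN3"),
               c("C", "H", "H", "H", "N", "H", "H", "H"), xyz)
}

#' Packaged probe templates
#'
#' One idealized copy of each of the seven cosolvent probes (benzene,
#' propane, methanol, formamide, acetaldehyde, acetate, methylammonium),
#' as atom tables with names, elements and internal coordinates in Å.
#'
#' @return Named list of data frames keyed by residue code (BENX, PRPN,
#'   MEOH, FORM, ACEH, ACET, MAMM).
#' @export
probe_templates <- function() {
  list(BENX = .benzene_template(),
       PRPN = .propane_template(),
       MEOH = .methanol_template(),
       FORM = .formamide_template(),
       ACEH = .acetaldehyde_template(),
       ACET = .acetate_template(),
       MAMM = .methylammonium_template())
}

#' One probe template by residue code
#' @param resname residue code, see [probe_templates()].
#' @export
probe_template <- function(resname) {
  t <- probe_templates()
  if (!resname %in% names(t))
    stop("no packaged template for residue '", resname, "' (have: ",
         paste(names(t), collapse = ", "), ")", call. = FALSE)
  t[[resname]]
}
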