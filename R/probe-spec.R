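## Probe definitions: which residues are restrained, the point used for
## intermolecular distances (a central atom or a mass-weighted centre),
## which type pairs receive walls, and the atom groups binned into
## density maps.

#' Distance anchors
#'
#' The intermolecular distance calculation is point-based: each probe
#' molecule is reduced to a single point, either one named atom
#' (`anchor_central_atom`) or the centre of mass of a set of atoms
#' (`anchor_com`; all atoms of the molecule when `atoms` is `NULL`).
#'
#' @param atom atom name used as the distance point.
#' @param atoms optional character vector restricting the COM to named
#'   atoms.
#' @return An object of class `anchor`.
#' @export
anchor_central_atom <- function(atom) {
  stopifnot(is.character(atom), length(atom) == 1L, nzchar(atom))
  structure(list(variant = "central_atom", atom = atom), class = "anchor")
}

#' @rdname anchor_central_atom
#' @export
anchor_com <- function(atoms = NULL) {
  if (!is.null(atoms))
    stopifnot(is.character(atoms), length(atoms) > 0, all(nzchar(atoms)))
  structure(list(variant = "center_of_mass", atoms = atoms), class = "anchor")
}

#' @export
print.anchor <- function(x, ...) {
  if (x$variant == "central_atom") {
    cat("anchor: central atom", x$atom, "\n")
  } else {
    cat("anchor: center of mass",
        if (is.null(x$atoms)) "(all atoms)" else
          paste0("(", paste(x$atoms, collapse = ","), ")"), "\n")
  }
  invisible(x)
}

#' Declare a probe type
#'
#' @param label unique label within a scheme (used in rule and PLUMED
#'   directive names).
#' @param resname residue code identifying the probe's molecules in
#'   structure files.
#' @param anchor an [anchor_central_atom()] or [anchor_com()].
#' @return Object of class `probe_type`.
#' @export
probe_type <- function(label, resname, anchor) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            grepl("^[A-Za-z][A-Za-z0-9_]*$", label),
            is.character(resname), length(resname) == 1L, nzchar(resname),
            inherits(anchor, "anchor"))
  structure(list(label = label, resname = resname, anchor = anchor),
            class = "probe_type")
}

#' Declare a wall rule between two probe types
#'
#' Pairs are unordered: `pair_rule("a", "b")` and `pair_rule("b", "a")`
#' are the same rule, and same-type rules (`a == b`) are allowed.
#'
#' @param type_a,type_b probe type labels.
#' @param wall optional [wall_params()] overriding the scheme wall for
#'   this rule.
#' @return Object of class `pair_rule`.
#' @export
pair_rule <- function(type_a, type_b, wall = NULL) {
  stopifnot(is.character(type_a), is.character(type_b))
  if (!is.null(wall)) stopifnot(inherits(wall, "wall_params"))
  structure(list(type_a = type_a, type_b = type_b, wall = wall),
            class = "pair_rule")
}

.rule_key <- function(rule) paste(sort(c(rule$type_a, rule$type_b)),
                                  collapse = "\r")

.rule_name <- function(rule) paste(c(rule$type_a, rule$type_b),
                                   collapse = "_")

#' Assemble a restraint scheme
#'
#' @param probe_types list of [probe_type()] objects; labels must be
#'   unique.
#' @param pair_rules list of [pair_rule()] objects referencing declared
#'   labels; duplicate unordered pairs are rejected.
#' @param production_wall,soft_wall the scheme's wall parameter sets
#'   ([wall_params()]).
#' @return Object of class `restraint_scheme`.
#' @export
restraint_scheme <- function(probe_types, pair_rules,
                             production_wall = cosolvr::production_wall(),
                             soft_wall = cosolvr::soft_wall()) {
  stopifnot(is.list(probe_types), length(probe_types) > 0,
            all(vapply(probe_types, inherits, logical(1), "probe_type")),
            is.list(pair_rules),
            all(vapply(pair_rules, inherits, logical(1), "pair_rule")),
            inherits(production_wall, "wall_params"),
            inherits(soft_wall, "wall_params"))
  labels <- vapply(probe_types, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate probe labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  for (r in pair_rules) {
    bad <- setdiff(c(r$type_a, r$type_b), labels)
    if (length(bad))
      stop("pair rule references undeclared probe type(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  keys <- vapply(pair_rules, .rule_key, character(1))
  if (anyDuplicated(keys))
    stop("duplicate pair rule(s) (pairs are unordered): ",
         paste(unique(gsub("\r", "-", keys[duplicated(keys)])), collapse = ", "),
         call. = FALSE)
  structure(list(probe_types = setNames(probe_types, labels),
                 pair_rules = pair_rules,
                 production_wall = production_wall,
                 soft_wall = soft_wall),
            class = "restraint_scheme")
}

#' @export
print.restraint_scheme <- function(x, ...) {
  cat(sprintf("restraint_scheme: %d probe types, %d pair rules\n",
              length(x$probe_types), length(x$pair_rules)))
  for (p in x$probe_types)
    cat(sprintf("  %-14s resname %-4s %s\n", p$label, p$resname,
                if (p$anchor$variant == "central_atom")
                  paste0("central atom ", p$anchor$atom) else "COM"))
  for (r in x$pair_rules)
    cat(sprintf("  wall: %s - %s\n", r$type_a, r$type_b))
  invisible(x)
}

#' The default seven-probe scheme
#'
#' The standard cosolvent mixture — benzene, propane, methanol,
#' formamide, acetaldehyde, acetate and methylammonium — with lower
#' walls on exactly the pairs prone to clustering: benzene–benzene,
#' propane–benzene, propane–propane (lipophilic aggregation) and
#' acetate–methylammonium (ion pairing).  Anchors: benzene by centre of
#' mass, propane by its central carbon, methylammonium by nitrogen,
#' acetate by the carboxylic carbon, formamide by its carbon; methanol
#' and acetaldehyde (never restrained, analysed only) by carbon.
#'
#' @return A [restraint_scheme()].
#' @export
default_scheme <- function() {
  restraint_scheme(
    probe_types = list(
      probe_type("benzene", "BENX", anchor_com()),
      probe_type("propane", "PRPN", anchor_central_atom("C2")),
      probe_type("methanol", "MEOH", anchor_central_atom("C")),
      probe_type("formamide", "FORM", anchor_central_atom("C")),
      probe_type("acetaldehyde", "ACEH", anchor_central_atom("C2")),
      probe_type("acetate", "ACET", anchor_central_atom("C2")),
      probe_type("methylammonium", "MAMM", anchor_central_atom("N"))
    ),
    pair_rules = list(
      pair_rule("benzene", "benzene"),
      pair_rule("propane", "benzene"),
      pair_rule("propane", "propane"),
      pair_rule("acetate", "methylammonium")
    )
  )
}

## ---- selection -------------------------------------------------------

#' Select the molecules of a probe type from a system
#'
#' Returns all molecules whose residue name matches the probe,
#' ordered by (chain, residue id); each is validated to contain the
#' anchor atom(s).
#'
#' @param system a [molecular_system()].
#' @param probe a [probe_type()].
#' @return List of molecule records (`mol_id`, `chain`, `resid`,
#'   `resname`, `atoms` = atom indices); empty with a warning when no
#'   molecule matches.
#' @export
select_probe_molecules <- function(system, probe) {
  stopifnot(inherits(system, "molecular_system"), inherits(probe, "probe_type"))
  tab <- system$mol_table
  hit <- which(tab$resname == probe$resname)
  if (!length(hit)) {
    warning("no molecules with residue name '", probe$resname,
            "' for probe '", probe$label, "'", call. = FALSE)
    return(list())
  }
  hit <- hit[order(tab$chain[hit], tab$resid[hit])]
  lapply(hit, function(m) {
    idx <- system$molecules[[m]]
    names_here <- system$atoms$name[idx]
    need <- switch(probe$anchor$variant,
                   central_atom = probe$anchor$atom,
                   center_of_mass = probe$anchor$atoms %||% character(0))
    miss <- setdiff(need, names_here)
    if (length(miss))
      stop("molecule ", tab$resname[m], " ", tab$resid[m],
           if (nzchar(tab$chain[m])) paste0(" chain ", tab$chain[m]),
           " lacks anchor atom(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    list(mol_id = tab$mol_id[m], chain = tab$chain[m], resid = tab$resid[m],
         resname = tab$resname[m], atoms = idx)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate restrained molecule pairs
#'
#' Same-type: all C(N,2) unordered pairs.  Cross-type: the full
#' N_A x N_B product.  Output order is lexicographic in (index_a,
#' index_b), so pair lists — and hence PLUMED labels — are stable.
#'
#' @param mols_a,mols_b molecule lists from [select_probe_molecules()];
#'   omit `mols_b` (or pass `NULL`) for a same-type rule.
#' @return Data frame with columns `a`, `b` (indices into the input
#'   lists); zero rows (with a warning) for degenerate inputs.
#' @export
enumerate_pairs <- function(mols_a, mols_b = NULL) {
  if (is.null(mols_b)) {
    n <- length(mols_a)
    if (n < 2) {
      warning("fewer than 2 molecules for a same-type rule: no pairs",
              call. = FALSE)
      return(data.frame(a = integer(0), b = integer(0)))
    }
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    out <- data.frame(a = idx[, "row"], b = idx[, "col"])
    return(out[order(out$a, out$b), , drop = FALSE])
  }
  na <- length(mols_a); nb <- length(mols_b)
  if (na == 0 || nb == 0) {
    warning("empty molecule list for a cross-type rule: no pairs",
            call. = FALSE)
    return(data.frame(a = integer(0), b = integer(0)))
  }
  data.frame(a = rep(seq_len(na), each = nb), b = rep(seq_len(nb), times = na))
}

## ---- anchor resolution -----------------------------------------------

#' Resolve a probe's anchors for analysis
#'
#' Precomputes, for each selected molecule, either the anchor atom's
#' index or the COM atom indices and masses, so anchor positions can be
#' evaluated cheaply on every trajectory frame.
#'
#' @param system a [molecular_system()].
#' @param probe a [probe_type()].
#' @param mols optional molecule list (defaults to
#'   [select_probe_molecules()]).
#' @return Object of class `anchor_set`.
#' @export
anchor_set <- function(system, probe, mols = NULL) {
  if (is.null(mols)) mols <- select_probe_molecules(system, probe)
  entries <- lapply(mols, function(m) {
    nm <- system$atoms$name[m$atoms]
    if (probe$anchor$variant == "central_atom") {
      list(kind = "atom", index = m$atoms[match(probe$anchor$atom, nm)])
    } else {
      sel <- if (is.null(probe$anchor$atoms)) seq_along(nm)
             else which(nm %in% probe$anchor$atoms)
      idx <- m$atoms[sel]
      list(kind = "com", index = idx,
           mass = element_mass(system$atoms$element[idx]))
    }
  })
  structure(list(probe = probe, mols = mols, entries = entries),
            class = "anchor_set")
}

#' Anchor positions for one frame
#'
#' @param aset an [anchor_set()].
#' @param positions N x 3 coordinate matrix (Å) for the whole system;
#'   defaults are not provided — pass `coords(system)` for the static
#'   structure.
#' @return M x 3 matrix of anchor points, one row per molecule.
#' @export
anchor_positions <- function(aset, positions) {
  stopifnot(inherits(aset, "anchor_set"))
  out <- matrix(0, length(aset$entries), 3)
  for (i in seq_along(aset$entries)) {
    e <- aset$entries[[i]]
    if (e$kind == "atom") {
      out[i, ] <- positions[e$index, ]
    } else {
      w <- e$mass / sum(e$mass)
      out[i, ] <- colSums(positions[e$index, , drop = FALSE] * w)
    }
  }
  out
}

#' Pool several anchor sets into one
#'
#' Concatenates the per-molecule anchors of multiple probe types into a
#' single set — e.g. benzene COMs plus propane central carbons for the
#' pooled hydrophobic aggregation statistic.
#'
#' @param ... [anchor_set()] objects.
#' @return An `anchor_set` whose molecules are the concatenation.
#' @export
combine_anchor_sets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) > 0,
            all(vapply(sets, inherits, logical(1), "anchor_set")))
  structure(list(probe = NULL,
                 mols = do.call(c, lapply(sets, `[[`, "mols")),
                 entries = do.call(c, lapply(sets, `[[`, "entries"))),
            class = "anchor_set")
}

## ---- density groups --------------------------------------------------

#' Declare a density atom group
#'
#' @param label one of `"hydrophobic"`, `"donor"`, `"acceptor"`,
#'   `"negative"`, `"positive"` (free labels are allowed for custom
#'   groups).
#' @param selectors data frame with columns `resname`, `atom`.
#' @return Object of class `density_group`.
#' @export
density_group <- function(label, selectors) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.data.frame(selectors), nrow(selectors) > 0,
            all(c("resname", "atom") %in% names(selectors)))
  structure(list(label = label, selectors = selectors),
            class = "density_group")
}

#' The five standard density atom groups
#'
#' Hydrophobic (propane and benzene carbons), hydrogen-bond donor
#' (formamide and methanol donor hydrogens), hydrogen-bond acceptor
#' (formamide, methanol and acetaldehyde oxygens), negatively charged
#' (acetate oxygens) and positively charged (methylammonium polar
#' hydrogens), resolved against the packaged probe templates' atom
#' names.
#'
#' @return Named list of five [density_group()] objects.
#' @export
default_density_groups <- function() {
  sel <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
      data.frame(resname = r[[1]], atom = r[[2]], stringsAsFactors = FALSE)))
  }
  list(
    hydrophobic = density_group("hydrophobic", sel(
      list("PRPN", c("C1", "C2", "C3")), list("BENX", paste0("C", 1:6)))),
    donor = density_group("donor", sel(
      list("FORM", c("HN1", "HN2")), list("MEOH", "HO"))),
    acceptor = density_group("acceptor", sel(
      list("FORM", "O"), list("MEOH", "O"), list("ACEH", "O"))),
    negative = density_group("negative", sel(list("ACET", c("O1", "O2")))),
    positive = density_group("positive", sel(
      list("MAMM", c("HN1", "HN2", "HN3"))))
  )
}

#' Atom indices matching a density group in a system
#'
#' @param system a [molecular_system()].
#' @param group a [density_group()].
#' @return Integer vector of atom indices (possibly empty).
#' @export
select_group_atoms <- function(system, group) {
  stopifnot(inherits(system, "molecular_system"),
            inherits(group, "density_group"))
  key <- paste(system$atoms$resname, system$atoms$name, sep = "\r")
  want <- paste(group$selectors$resname, group$selectors$atom, sep = "\r")
  which(key %in% want)
}

## ---- scheme config files ---------------------------------------------

.anchor_from_config <- function(cfg) {
  type <- cfg$type %||% stop("anchor needs a 'type' field", call. = FALSE)
  if (!is.null(cfg$atom) && !is.character(cfg$atom))
    stop("anchor atom name must be a string (quote bare Y/N/ON/OFF ",
         "atom names in YAML)", call. = FALSE)
  switch(type,
         central_atom = anchor_central_atom(cfg$atom),
         com = anchor_com(if (is.null(cfg$atoms)) NULL
                          else as.character(unlist(cfg$atoms))),
         stop("unknown anchor type '", type, "'", call. = FALSE))
}

.wall_from_config <- function(cfg) {
  wall_params(k = cfg$k, a = cfg$a, s = cfg$s %||% 1, e = cfg$e %||% 4,
              energy = cfg$energy %||% "kJ/mol",
              length = cfg$length %||% "nm")
}

#' Load a restraint scheme from a YAML config file
#'
#' The shipped default scheme lives at
#' `system.file("extdata", "default_scheme.yaml", package = "cosolvr")`.
#'
#' @param path YAML file with `probes`, `pair_rules` and `walls` keys.
#' @return A [restraint_scheme()].
#' @export
load_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  probes <- lapply(cfg$probes, function(p)
    probe_type(p$label, p$resname, .anchor_from_config(p$anchor)))
  rules <- lapply(cfg$pair_rules, function(r) {
    r <- as.character(unlist(r))
    if (length(r) != 2) stop("pair rule must name exactly two probe types",
                             call. = FALSE)
    pair_rule(r[1], r[2])
  })
  restraint_scheme(
    probes, rules,
    production_wall = if (is.null(cfg$walls$production)) production_wall()
                      else .wall_from_config(cfg$walls$production),
    soft_wall = if (is.null(cfg$walls$soft)) soft_wall()
                else .wall_from_config(cfg$walls$soft))
}
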