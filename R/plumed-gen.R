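## Emission of the PLUMED restraint script: one COM per COM-anchored
## molecule, one DISTANCE per enumerated pair, one grouped LOWER_WALLS
## per pair rule, and a PRINT of all bias values.  Rendering is fully
## deterministic (fixed ordering, fixed 6-significant-digit numeric
## formatting, no timestamps) so re-runs are byte-identical.

.fmt_num <- function(x) {
  # 6 significant digits, no scientific notation for the magnitudes
  # that occur in these scripts
  out <- formatC(x, format = "fg", digits = 6, flag = "#")
  out <- sub("\\.?0+$", "", out)
  out[x == round(x) & abs(x) < 1e15] <- format(round(x[x == round(x) & abs(x) < 1e15]),
                                               scientific = FALSE, trim = TRUE)
  out
}

#' Construct a PLUMED directive
#'
#' @param label unique directive label.
#' @param action PLUMED action name (`"COM"`, `"DISTANCE"`,
#'   `"LOWER_WALLS"`, `"PRINT"`).
#' @param keywords named list, rendered in order as `KEY=value`.
#' @return Object of class `plumed_directive`.
#' @export
plumed_directive <- function(label, action, keywords = list()) {
  stopifnot(is.character(label), length(label) == 1L,
            grepl("^[A-Za-z_][A-Za-z0-9_]*$", label),
            is.character(action), length(action) == 1L,
            is.list(keywords))
  structure(list(label = label, action = action, keywords = keywords),
            class = "plumed_directive")
}

.render_directive <- function(d) {
  kw <- vapply(seq_along(d$keywords), function(i) {
    v <- d$keywords[[i]]
    if (is.numeric(v)) v <- paste(.fmt_num(v), collapse = ",")
    else v <- paste(v, collapse = ",")
    paste0(names(d$keywords)[i], "=", v)
  }, character(1))
  paste(c(paste0(d$label, ":"), d$action, kw), collapse = " ")
}

# Resolve every probe type of a scheme against a system: selected
# molecules, per-molecule anchor references (a bare atom serial for
# central-atom anchors, a COM label otherwise) and any COM directives.
.resolve_scheme_anchors <- function(system, scheme) {
  out <- list()
  for (p in scheme$probe_types) {
    mols <- withCallingHandlers(
      select_probe_molecules(system, p),
      warning = function(w) invokeRestart("muffleWarning"))
    refs <- character(length(mols))
    coms <- list()
    for (i in seq_along(mols)) {
      m <- mols[[i]]
      nm <- system$atoms$name[m$atoms]
      if (p$anchor$variant == "central_atom") {
        refs[i] <- as.character(m$atoms[match(p$anchor$atom, nm)])
      } else {
        sel <- if (is.null(p$anchor$atoms)) seq_along(nm)
               else which(nm %in% p$anchor$atoms)
        lab <- sprintf("%s_%d_com", p$label, i)
        coms[[length(coms) + 1]] <-
          plumed_directive(lab, "COM", list(ATOMS = m$atoms[sel]))
        refs[i] <- lab
      }
    }
    out[[p$label]] <- list(probe = p, mols = mols, refs = refs, coms = coms)
  }
  out
}

#' Emit COM anchor directives
#'
#' One `COM` directive per molecule of each COM-anchored probe type,
#' labelled `<type>_<i>_com` with `ATOMS` set to the molecule's anchor
#' atom serials.  Central-atom anchors produce no directive — their
#' serial is referenced directly by `DISTANCE`.
#'
#' @param system a [molecular_system()].
#' @param scheme a [restraint_scheme()].
#' @return List of [plumed_directive()]s (possibly empty).
#' @export
emit_anchors <- function(system, scheme) {
  res <- .resolve_scheme_anchors(system, scheme)
  out <- unlist(unname(lapply(res, `[[`, "coms")), recursive = FALSE)
  if (is.null(out)) list() else out
}

#' Emit DISTANCE directives for one rule's pairs
#'
#' @param pairs pair table from [enumerate_pairs()].
#' @param refs_a,refs_b anchor reference vectors (atom serials or COM
#'   labels) for the rule's two probe types.
#' @param rule_name rule identifier used in labels `d_<rule>_<j>`.
#' @return List of [plumed_directive()]s.
#' @export
emit_distances <- function(pairs, refs_a, refs_b, rule_name) {
  lapply(seq_len(nrow(pairs)), function(j) {
    plumed_directive(sprintf("d_%s_%d", rule_name, j), "DISTANCE",
                     list(ATOMS = c(refs_a[pairs$a[j]], refs_b[pairs$b[j]])))
  })
}

#' Emit one grouped LOWER_WALLS directive for a rule
#'
#' The engine's lower wall adds `k*((x - a + offset)/s)^e` below `a`;
#' parameters are emitted per argument (`AT`, `KAPPA`, `EXP`, `EPS`,
#' `OFFSET` lists of the same arity as `ARG`), always in engine units
#' (kJ/mol, nm).
#'
#' @param distance_labels labels of the rule's DISTANCE directives.
#' @param wall a [wall_params()] in any unit system (converted).
#' @param rule_name rule identifier; the directive label is
#'   `wall_<rule>`.
#' @return A [plumed_directive()], or `NULL` (with a warning) when
#'   `distance_labels` is empty.
#' @export
emit_lower_walls <- function(distance_labels, wall, rule_name) {
  if (!length(distance_labels)) {
    warning("rule '", rule_name, "' has no distances; wall omitted",
            call. = FALSE)
    return(NULL)
  }
  w <- convert_wall_params(wall, energy = "kJ/mol", length = "nm")
  n <- length(distance_labels)
  plumed_directive(paste0("wall_", rule_name), "LOWER_WALLS", list(
    ARG = distance_labels,
    AT = rep(w$a, n), KAPPA = rep(w$k, n), EXP = rep(w$e, n),
    EPS = rep(w$s, n), OFFSET = rep(0, n)))
}

#' Emit the bias PRINT directive
#'
#' @param wall_labels labels of the LOWER_WALLS directives.
#' @param stride print stride in MD steps (default 500).
#' @param out_file bias output file name written by the engine.
#' @return A [plumed_directive()], or `NULL` (with a warning) when
#'   there are no walls.
#' @export
emit_print <- function(wall_labels, stride = 500, out_file = "restraint_bias.dat") {
  if (!length(wall_labels)) {
    warning("no walls defined; PRINT omitted", call. = FALSE)
    return(NULL)
  }
  plumed_directive("bias_print", "PRINT", list(
    ARG = paste0(wall_labels, ".bias"), STRIDE = stride, FILE = out_file))
}

# Small deterministic content hash (polynomial rolling hash modulo a
# Mersenne prime) for the script header: identical inputs give
# identical provenance strings, with no timestamps involved.
.content_hash <- function(text) {
  bytes <- as.numeric(charToRaw(paste(text, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Generate the complete PLUMED restraint script
#'
#' Anchors, per-pair distances, per-rule grouped lower walls and the
#' bias print, in that order.  Rules whose probe types have too few
#' molecules are skipped with a warning.  `mode = "soft"` swaps in the
#' scheme's soft wall parameter set (weaker, quadratic), used during
#' early equilibration.
#'
#' @param system a [molecular_system()].
#' @param scheme a [restraint_scheme()].
#' @param mode `"production"` or `"soft"`.
#' @param stride bias print stride (MD steps).
#' @param bias_file engine-side bias output file name.
#' @return Object of class `plumed_script` (header + ordered directive
#'   list); render with [render_plumed()] or write with
#'   [write_plumed()].
#' @export
generate_plumed <- function(system, scheme, mode = c("production", "soft"),
                            stride = 500, bias_file = "restraint_bias.dat") {
  mode <- match.arg(mode)
  stopifnot(inherits(system, "molecular_system"),
            inherits(scheme, "restraint_scheme"))
  res <- .resolve_scheme_anchors(system, scheme)
  directives <- unlist(unname(lapply(res, `[[`, "coms")), recursive = FALSE)
  if (is.null(directives)) directives <- list()
  walls <- list()
  rule_info <- list()
  for (r in scheme$pair_rules) {
    rn <- .rule_name(r)
    a <- res[[r$type_a]]; b <- res[[r$type_b]]
    same <- identical(r$type_a, r$type_b)
    if ((same && length(a$mols) < 2) ||
        (!same && (length(a$mols) == 0 || length(b$mols) == 0))) {
      warning("rule '", rn, "' skipped: not enough molecules (",
              r$type_a, ": ", length(a$mols), ", ",
              r$type_b, ": ", length(b$mols), ")", call. = FALSE)
      rule_info[[rn]] <- 0L
      next
    }
    pairs <- if (same) enumerate_pairs(a$mols)
             else enumerate_pairs(a$mols, b$mols)
    dd <- emit_distances(pairs, a$refs, b$refs, rn)
    directives <- c(directives, dd)
    wall <- r$wall %||% switch(mode, production = scheme$production_wall,
                               soft = scheme$soft_wall)
    wd <- emit_lower_walls(vapply(dd, `[[`, character(1), "label"), wall, rn)
    walls <- c(walls, list(wd))
    directives <- c(directives, list(wd))
    rule_info[[rn]] <- nrow(pairs)
  }
  pr <- emit_print(vapply(walls, `[[`, character(1), "label"),
                   stride = stride, out_file = bias_file)
  if (!is.null(pr)) directives <- c(directives, list(pr))
  body <- vapply(directives, .render_directive, character(1))
  header <- c("# PLUMED restraint script generated by cosolvr",
              paste0("# mode: ", mode),
              paste0("# content-hash: ", .content_hash(body)))
  structure(list(header = header, directives = directives,
                 mode = mode, rule_pairs = rule_info),
            class = "plumed_script")
}

#' Render a PLUMED script to text lines
#' @param script a `plumed_script` from [generate_plumed()].
#' @return Character vector of lines.
#' @export
render_plumed <- function(script) {
  stopifnot(inherits(script, "plumed_script"))
  c(script$header,
    vapply(script$directives, .render_directive, character(1)))
}

#' @export
print.plumed_script <- function(x, ...) {
  acts <- vapply(x$directives, `[[`, character(1), "action")
  tab <- table(factor(acts, levels = c("COM", "DISTANCE", "LOWER_WALLS", "PRINT")))
  cat(sprintf("plumed_script (%s): %d COM, %d DISTANCE, %d LOWER_WALLS, %d PRINT\n",
              x$mode, tab["COM"], tab["DISTANCE"], tab["LOWER_WALLS"],
              tab["PRINT"]))
  invisible(x)
}

#' Write a PLUMED script to file
#' @param script a `plumed_script`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plumed <- function(script, path) {
  writeLines(render_plumed(script), path)
  invisible(path)
}

#' Parse rendered PLUMED lines back into directives
#'
#' A light parser for the dialect this package emits (`label: ACTION
#' KEY=value ...`), used by the grammar checker and the
#' script-vs-oracle consistency tests.
#'
#' @param lines character vector (comments and blank lines ignored).
#' @return List of [plumed_directive()]s.
#' @export
parse_plumed <- function(lines) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  lapply(seq_along(lines), function(i) {
    ln <- trimws(lines[i])
    m <- regmatches(ln, regexec(
      "^([A-Za-z_][A-Za-z0-9_]*):[[:space:]]+([A-Z_]+)(([[:space:]]+[A-Z_]+=[^[:space:]]+)*)[[:space:]]*$",
      ln))[[1]]
    if (!length(m))
      stop("line ", i, " does not match 'label: ACTION KEY=value ...': ",
           ln, call. = FALSE)
    kw_raw <- regmatches(m[4], gregexpr("[A-Z_]+=[^[:space:]]+", m[4]))[[1]]
    kw <- list()
    for (pair in kw_raw) {
      eq <- regexpr("=", pair)
      kw[[substr(pair, 1, eq - 1)]] <-
        strsplit(substr(pair, eq + 1, nchar(pair)), ",")[[1]]
    }
    plumed_directive(m[2], m[3], kw)
  })
}

#' Grammar-check a rendered PLUMED script
#'
#' Verifies that every non-comment line matches
#' `label: ACTION KEY=value ...`, that labels are unique, and that
#' every reference (DISTANCE `ATOMS` label entries, `ARG` entries with
#' an optional `.bias` suffix) is defined earlier in the file
#' (topological order).  Numeric `ATOMS` entries are taken as atom
#' serials and must be positive integers.
#'
#' @param lines character vector, e.g. from [render_plumed()] or
#'   `readLines()`.
#' @return `TRUE` invisibly; problems are errors.
#' @export
validate_plumed <- function(lines) {
  dirs <- parse_plumed(lines)
  seen <- character(0)
  for (d in dirs) {
    if (d$label %in% seen) stop("duplicate label '", d$label, "'", call. = FALSE)
    for (key in names(d$keywords)) {
      vals <- d$keywords[[key]]
      if (key == "ATOMS") {
        for (v in vals) {
          if (grepl("^[0-9]+$", v)) {
            if (as.numeric(v) < 1) stop("atom serial < 1 in ", d$label,
                                        call. = FALSE)
          } else if (!(v %in% seen)) {
            stop("directive '", d$label, "' references undefined label '",
                 v, "'", call. = FALSE)
          }
        }
      }
      if (key == "ARG") {
        for (v in sub("\\.bias$", "", vals)) {
          if (!(v %in% seen))
            stop("directive '", d$label, "' references undefined label '",
                 v, "'", call. = FALSE)
        }
      }
    }
    seen <- c(seen, d$label)
  }
  invisible(TRUE)
}

#' Recover wall parameters from an emitted LOWER_WALLS directive
#'
#' Reads the first argument's `AT`/`KAPPA`/`EXP`/`EPS` values back into
#' a [wall_params()] in engine units — the bridge used to check that
#' the emitted script and the analytic bias model agree.
#'
#' @param directive a `LOWER_WALLS` [plumed_directive()].
#' @return A `wall_params` in kJ/mol, nm.
#' @export
wall_params_from_directive <- function(directive) {
  stopifnot(inherits(directive, "plumed_directive"),
            directive$action == "LOWER_WALLS")
  num1 <- function(key) as.numeric(directive$keywords[[key]][1])
  wall_params(k = num1("KAPPA"), a = num1("AT"), s = num1("EPS"),
              e = num1("EXP"), energy = "kJ/mol", length = "nm")
}
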