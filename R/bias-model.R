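#' Wall (lower-wall bias) parameters
#'
#' A one-sided restraint potential acting on an intermolecular distance
#' \eqn{x}: \deqn{V(x) = k \left(\frac{x - a}{s}\right)^e \quad (x < a),
#' \qquad V(x) = 0 \quad (x \ge a).}
#' The wall adds energy only when the distance drops below the wall
#' location \eqn{a}, pushing probe pairs apart and preventing
#' hydrophobic aggregation while leaving well-separated pairs untouched.
#'
#' Parameters carry an explicit unit system because the literature
#' quotes them in kcal/mol and ångström while the GROMACS/PLUMED engine
#' consumes kJ/mol and nanometres.  The force-constant unit depends on
#' the exponent: \eqn{k} has units energy·length^-e.
#'
#' @param k wall force constant, >= 0, in `energy`·`length`^-e units.
#' @param a wall location (> 0) in `length` units.
#' @param s dimensionless rescaling factor (> 0).
#' @param e wall exponent (>= 2).  Even exponents give a purely
#'   repulsive wall; odd exponents are accepted with a warning because
#'   the branch below `a` then changes sign with `(x - a)`.
#' @param energy `"kcal/mol"` or `"kJ/mol"`.
#' @param length `"angstrom"` or `"nm"`.
#' @return An object of class `wall_params`.
#' @examples
#' w <- wall_params(k = 0.5, a = 8, s = 1, e = 4)
#' wall_energy(7, w)   # 0.5 kcal/mol
#' wall_energy(8, w)   # 0 at and beyond the wall
#' @export
wall_params <- function(k, a, s = 1, e = 4,
                        energy = c("kcal/mol", "kJ/mol"),
                        length = c("angstrom", "nm")) {
  energy <- match.arg(energy)
  length <- match.arg(length)
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k >= 0)
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a), a > 0)
  stopifnot(is.numeric(s), length(s) == 1L, is.finite(s), s > 0)
  stopifnot(is.numeric(e), length(e) == 1L, is.finite(e), e >= 2)
  if (e %% 2 != 0) {
    warning("odd wall exponent e = ", e,
            ": the wall is not purely repulsive below a", call. = FALSE)
  }
  structure(
    list(k = k, a = a, s = s, e = e, energy = energy, length = length),
    class = "wall_params"
  )
}

#' @export
print.wall_params <- function(x, ...) {
  cat(sprintf("wall_params: k = %g %s %s^-%g, a = %g %s, s = %g, e = %g\n",
              x$k, x$energy, x$length, x$e, x$a, x$length, x$s, x$e))
  invisible(x)
}

KCAL_PER_KJ <- 1 / 4.184
ANGSTROM_PER_NM <- 10

.energy_factor <- function(from, to) {
  if (from == to) return(1)
  if (from == "kJ/mol" && to == "kcal/mol") return(KCAL_PER_KJ)
  1 / KCAL_PER_KJ
}

.length_factor <- function(from, to) {
  if (from == to) return(1)
  if (from == "nm" && to == "angstrom") return(ANGSTROM_PER_NM)
  1 / ANGSTROM_PER_NM
}

.check_units <- function(params, energy, length) {
  if (!is.null(energy) && params$energy != energy)
    stop("energy unit mismatch: parameters in ", params$energy,
         ", value in ", energy, call. = FALSE)
  if (!is.null(length) && params$length != length)
    stop("length unit mismatch: parameters in ", params$length,
         ", value in ", length, call. = FALSE)
}

#' Evaluate the wall potential
#'
#' @param x distance(s), same length unit as `params`; vectorized.
#' @param params a [wall_params()] object.
#' @param length optional unit tag for `x` (`"angstrom"`/`"nm"`); when
#'   given it must match the parameter unit system.
#' @return Energy value(s) in the parameter energy unit; zero at and
#'   beyond the wall location.
#' @export
wall_energy <- function(x, params, length = NULL) {
  stopifnot(inherits(params, "wall_params"), is.numeric(x), all(x >= 0))
  .check_units(params, energy = NULL, length = length)
  v <- params$k * ((x - params$a) / params$s)^params$e
  v[x >= params$a] <- 0
  v
}

#' Wall force along the distance coordinate
#'
#' Analytic derivative \eqn{-dV/dx}: for \eqn{x < a},
#' \eqn{-k\,e\,((x-a)/s)^{e-1}/s}; zero otherwise.  For even exponents
#' the force is positive (distance-increasing, i.e. repulsive) below
#' the wall.
#'
#' @inheritParams wall_energy
#' @return Force value(s), energy/length units.
#' @export
wall_force <- function(x, params, length = NULL) {
  stopifnot(inherits(params, "wall_params"), is.numeric(x), all(x >= 0))
  .check_units(params, energy = NULL, length = length)
  f <- -params$k * params$e *
    ((x - params$a) / params$s)^(params$e - 1) / params$s
  f[x >= params$a] <- 0
  f
}

#' Convert wall parameters between unit systems
#'
#' The force constant scales by the energy factor times the length
#' factor to the power \eqn{-e} (its units depend on the exponent); the
#' wall location scales by the length factor; `s` and `e` are
#' dimensionless and unchanged.  Round trips are identities to within
#' floating-point precision.
#'
#' @param params a [wall_params()] object.
#' @param energy,length target units.
#' @return A `wall_params` object in the target unit system.
#' @examples
#' engine <- wall_params(20000, 0.8, 1, 4, energy = "kJ/mol", length = "nm")
#' convert_wall_params(engine, "kcal/mol", "angstrom")  # k ~ 0.478, a = 8
#' @export
convert_wall_params <- function(params,
                                energy = c("kcal/mol", "kJ/mol"),
                                length = c("angstrom", "nm")) {
  stopifnot(inherits(params, "wall_params"))
  energy <- match.arg(energy)
  length <- match.arg(length)
  ef <- .energy_factor(params$energy, energy)
  lf <- .length_factor(params$length, length)
  out <- params
  out$k <- params$k * ef * lf^(-params$e)
  out$a <- params$a * lf
  out$energy <- energy
  out$length <- length
  out
}

#' Canonical production wall parameters
#'
#' The shipped default restraint: KAPPA = 20000 kJ mol^-1 nm^-4,
#' AT = 0.8 nm, EPS = 1, EXP = 4 — equivalently about
#' 0.478 kcal mol^-1 Å^-4 at 8.0 Å.  Stored in engine units so emitted
#' scripts contain round numbers.
#'
#' @return A `wall_params` object in kJ/mol, nm.
#' @export
production_wall <- function() {
  wall_params(k = 20000, a = 0.8, s = 1, e = 4,
              energy = "kJ/mol", length = "nm")
}

#' Soft wall parameters for gentle equilibration
#'
#' A weak quadratic wall (KAPPA = 10 kJ mol^-1 nm^-2, EXP = 2, about
#' 0.024 kcal mol^-1 Å^-2) used during early equilibration so that probe
#' molecules that start close together are not hit with large forces.
#'
#' @return A `wall_params` object in kJ/mol, nm.
#' @export
soft_wall <- function() {
  wall_params(k = 10, a = 0.8, s = 1, e = 2,
              energy = "kJ/mol", length = "nm")
}
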