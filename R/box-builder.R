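## Synthetic cosolvent systems and trajectories: the fixture engine
## that lets restraint generation and the analysis stack be exercised
## end-to-end without an MD engine, plus a toy Brownian-dynamics
## surrogate demonstrating that the lower-wall bias suppresses
## hydrophobic aggregation.

AVOGADRO <- 6.02214076e23
LITRE_PER_A3 <- 1e-27

#' Probe copies for a target molar concentration
#'
#' Round-half-up of `conc` x (volume in litres) x Avogadro's number.
#' The default mixture concentration is 0.25 M per probe type.
#'
#' @param conc molar concentration (mol/L), >= 0.
#' @param box_volume box volume in cubic ångström.
#' @return Integer molecule count.
#' @examples
#' molecules_for_concentration(0.25, 100^3)  # 151
#' @export
molecules_for_concentration <- function(conc, box_volume) {
  stopifnot(is.numeric(conc), conc >= 0, is.numeric(box_volume),
            box_volume > 0)
  as.integer(floor(conc * box_volume * LITRE_PER_A3 * AVOGADRO + 0.5))
}

# Uniform random rotation matrix via Shoemake's quaternion method.
.random_rotation <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

.uniform_point <- function(box) {
  runif(3) %*% box$vectors
}

#' Insert probe molecules into a system by clash-free random placement
#'
#' Each copy gets a uniform random position (fractional coordinates)
#' and a uniform random rotation, and is rejected and resampled while
#' any heavy-atom minimum-image distance to already-placed heavy atoms
#' is below `clash_cutoff`.  Reproducible for a given `seed`.
#'
#' @param base a [molecular_system()] to insert into, or a [make_box()]
#'   for an initially empty box.
#' @param counts named integer vector: copies per residue code.
#' @param seed RNG seed (mandatory).
#' @param clash_cutoff heavy-atom clash distance, Å (default 2.0).
#' @param max_attempts placement attempts per molecule before giving up
#'   (default 10000) with an error suggesting a lower concentration.
#' @param templates named list of template atom tables (default
#'   [probe_templates()]); each needs `name`, `element`, `x`, `y`, `z`.
#' @return A [molecular_system()].
#' @export
insert_probes <- function(base, counts, seed, clash_cutoff = 2.0,
                          max_attempts = 10000L,
                          templates = probe_templates()) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0),
            is.numeric(seed), length(seed) == 1L)
  if (inherits(base, "sim_box")) {
    box <- base
    atoms <- NULL
    next_resid <- 1L
  } else {
    stopifnot(inherits(base, "molecular_system"))
    box <- base$box
    atoms <- base$atoms[, c("name", "resname", "resid", "chain",
                            "x", "y", "z", "element")]
    next_resid <- max(atoms$resid) + 1L
  }
  miss <- setdiff(names(counts), names(templates))
  if (length(miss))
    stop("no template for residue(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  set.seed(as.integer(seed))
  heavy <- if (is.null(atoms)) matrix(numeric(0), 0, 3) else
    as.matrix(atoms[atoms$element != "H", c("x", "y", "z")])
  new_rows <- list()
  for (res in names(counts)) {
    tmpl <- templates[[res]]
    txyz <- as.matrix(tmpl[, c("x", "y", "z")])
    txyz <- sweep(txyz, 2, colMeans(txyz))  # centre template
    t_heavy <- tmpl$element != "H"
    for (copy in seq_len(counts[[res]])) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        pos <- txyz %*% t(.random_rotation())
        pos <- sweep(pos, 2, as.numeric(.uniform_point(box)), "+")
        ok <- TRUE
        if (nrow(heavy) > 0 && any(t_heavy)) {
          d <- min_image_dist_matrix(pos[t_heavy, , drop = FALSE], heavy, box)
          ok <- all(d >= clash_cutoff)
        }
        if (ok) {
          new_rows[[length(new_rows) + 1]] <- data.frame(
            name = tmpl$name, resname = res, resid = next_resid,
            chain = "", x = pos[, 1], y = pos[, 2], z = pos[, 3],
            element = tmpl$element, stringsAsFactors = FALSE)
          heavy <- rbind(heavy, pos[t_heavy, , drop = FALSE])
          next_resid <- next_resid + 1L
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place ", res, " copy ", copy, " after ",
             max_attempts, " attempts; the box is too crowded - lower the ",
             "concentration or the clash cutoff", call. = FALSE)
    }
  }
  all_atoms <- rbind(atoms, do.call(rbind, new_rows))
  if (is.null(all_atoms) || nrow(all_atoms) == 0)
    stop("nothing to insert and no base atoms", call. = FALSE)
  molecular_system(all_atoms, box)
}

#' Build a probe-only box at given concentrations
#'
#' Convenience wrapper: computes per-type copy numbers with
#' [molecules_for_concentration()] and fills an empty cubic box with
#' [insert_probes()].
#'
#' @param concentrations named vector of molar concentrations per
#'   residue code (default: 0.25 M of each packaged probe).
#' @param box_edge cubic box edge, Å.
#' @param seed RNG seed.
#' @param ... passed to [insert_probes()].
#' @return A [molecular_system()].
#' @export
build_probe_box <- function(concentrations = setNames(rep(0.25, 7),
                                                      names(probe_templates())),
                            box_edge = 60, seed, ...) {
  box <- make_box(rep(box_edge, 3))
  counts <- vapply(concentrations, molecules_for_concentration,
                   integer(1), box_volume = box_volume(box))
  insert_probes(box, counts, seed = seed, ...)
}

## ---- synthetic trajectories ------------------------------------------

# Rigid-body re-placement of every molecule of a system at given
# centre points with random orientations.
.place_molecules <- function(system, centers, rotate = TRUE) {
  pos <- coords(system)
  for (i in seq_along(system$molecules)) {
    idx <- system$molecules[[i]]
    local <- pos[idx, , drop = FALSE]
    local <- sweep(local, 2, colMeans(local))
    if (rotate) local <- local %*% t(.random_rotation())
    pos[idx, ] <- sweep(local, 2, centers[i, ], "+")
  }
  pos
}

# Draw n centre points uniformly, enforcing pairwise minimum-image
# separation >= min_sep by rejection.
.dispersed_centers <- function(n, box, min_sep, max_attempts = 10000L) {
  centers <- matrix(0, n, 3)
  placed <- 0
  while (placed < n) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      p <- as.numeric(.uniform_point(box))
      if (placed == 0 ||
          all(min_image_dist_matrix(rbind(p), centers[seq_len(placed), ,
                                                      drop = FALSE], box)
              >= min_sep)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not disperse ", n, " molecules at separation ",
                  min_sep, " A", call. = FALSE)
    placed <- placed + 1
    centers[placed, ] <- p
  }
  centers
}

# Draw n centre points inside a sphere of given radius around `center`,
# each (after the first) within `link_dist` of an already-placed point,
# so every molecule is guaranteed a neighbour below the aggregation
# cutoff.
.clustered_centers <- function(n, center, radius, link_dist) {
  centers <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    repeat {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      p <- center + radius * runif(1)^(1 / 3) * u
      if (i == 1 ||
          min(sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) - p)^2)))
          < link_dist) break
    }
    centers[i, ] <- p
  }
  centers
}

#' Generate a ground-truthed synthetic trajectory
#'
#' `dispersed` mode re-draws clash-free uniform rigid placements of
#' every molecule each frame — an ideal-gas-like trajectory whose RDF
#' is flat and whose aggregation fraction is governed by Poisson
#' neighbour statistics.  `clustered` mode draws molecule centres
#' within a sphere of radius `cluster_radius` around the box centre,
#' linking each molecule to a previously placed one at under
#' `link_dist`, so the 7 Å aggregation fraction is 1 on every frame by
#' construction.
#'
#' @param system a [molecular_system()]; every molecule is re-placed.
#' @param mode `"dispersed"` or `"clustered"`.
#' @param n_frames number of frames.
#' @param seed RNG seed (mandatory).
#' @param min_sep dispersed-mode minimum centre separation, Å.
#' @param cluster_radius clustered-mode sphere radius, Å (default 6).
#' @param link_dist clustered-mode neighbour guarantee distance, Å
#'   (default 6, comfortably below the 7 Å criterion).
#' @return A [frame_source()].
#' @export
make_synthetic_trajectory <- function(system, mode = c("dispersed", "clustered"),
                                      n_frames, seed, min_sep = 2.0,
                                      cluster_radius = 6.0, link_dist = 6.0) {
  mode <- match.arg(mode)
  stopifnot(inherits(system, "molecular_system"), n_frames >= 1)
  set.seed(as.integer(seed))
  n_mol <- length(system$molecules)
  center <- colSums(system$box$vectors) / 2
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    centers <- switch(mode,
      dispersed = .dispersed_centers(n_mol, system$box, min_sep),
      clustered = .clustered_centers(n_mol, center, cluster_radius, link_dist))
    frames[[f]] <- .place_molecules(system, centers)
  }
  frame_source(frames, system$box)
}

## ---- toy Brownian-dynamics surrogate ---------------------------------

#' Parameters for the toy Brownian-dynamics surrogate
#'
#' A desk-scale overdamped-Langevin model of point particles in a
#' periodic cubic box: hydrophobic particles attract each other through
#' a short-range polynomial well (mimicking the hydrophobic effect),
#' every pair has a soft repulsive core, and — when `bias` is on — the
#' lower-wall force from [wall_force()] acts on every
#' hydrophobic–hydrophobic pair distance, exactly as the emitted PLUMED
#' restraints would.  This is a qualitative surrogate for the
#' aggregation contrast, not a molecular-mechanics simulation.
#'
#' @param n_steps integration steps (default 6000).
#' @param dt time step in reduced units (default 0.05); with friction 1
#'   and kT at 300 K the per-step RMS displacement is about 0.24 Å.
#' @param friction friction coefficient (kcal/mol time/Å^2 scale;
#'   default 1).
#' @param kT thermal energy, kcal/mol (default 0.0019872 x 300).
#' @param well_depth hydrophobic attraction depth, kcal/mol (default 4).
#' @param well_range attraction range, Å (default 7; zero force
#'   beyond).
#' @param core_sigma soft-core diameter, Å (default 3).
#' @param core_k soft-core stiffness, kcal/mol/Å^2 (default 5).
#' @param bias logical: apply the wall restraint force.
#' @param wall a [wall_params()]; default the production set converted
#'   to kcal/mol, Å.
#' @param box_edge cubic box edge, Å (default 40).
#' @param save_every record a frame every this many steps (default 20).
#' @param max_move clamp on the per-step deterministic drift of any
#'   particle, Å (default 1.0).  The quartic wall is stiff at short
#'   range; clamping the drift — a standard Brownian-dynamics
#'   stabilization — keeps the integrator stable without shrinking the
#'   time step.  Set to `Inf` to disable.
#' @param seed RNG seed (mandatory, no default).
#' @return Object of class `toy_params`.
#' @export
toy_params <- function(n_steps = 6000, dt = 0.05, friction = 1,
                       kT = 0.0019872 * 300, well_depth = 4, well_range = 7,
                       core_sigma = 3, core_k = 5, bias = FALSE,
                       wall = convert_wall_params(production_wall(),
                                                  "kcal/mol", "angstrom"),
                       box_edge = 40, save_every = 20, max_move = 1.0, seed) {
  stopifnot(n_steps > 0, dt > 0, friction > 0, kT > 0, well_depth >= 0,
            well_range > 0, core_sigma > 0, core_k >= 0,
            is.logical(bias), inherits(wall, "wall_params"),
            box_edge > 0, save_every > 0, max_move > 0)
  if (missing(seed)) stop("toy_params: seed is mandatory", call. = FALSE)
  structure(list(n_steps = as.integer(n_steps), dt = dt, friction = friction,
                 kT = kT, well_depth = well_depth, well_range = well_range,
                 core_sigma = core_sigma, core_k = core_k, bias = bias,
                 wall = convert_wall_params(wall, "kcal/mol", "angstrom"),
                 box_edge = box_edge, save_every = as.integer(save_every),
                 max_move = max_move, seed = as.integer(seed)),
            class = "toy_params")
}

#' Run the toy Brownian-dynamics surrogate
#'
#' Overdamped-Langevin update `x <- x + F/friction * dt +
#' sqrt(2 kT dt / friction) * N(0,1)` under minimum-image pair forces
#' (see [toy_params()]).  Reproducible for a given seed; identical
#' seeds give byte-identical trajectories.
#'
#' @param n_particles total particle count.
#' @param params a [toy_params()].
#' @param hydrophobic logical vector flagging hydrophobic particles
#'   (default: all).
#' @return List with `frames` (a [frame_source()], one atom per
#'   particle), `hydrophobic`, and `params`.
#' @export
toy_brownian <- function(n_particles, params, hydrophobic = rep(TRUE, n_particles)) {
  stopifnot(inherits(params, "toy_params"), n_particles >= 2,
            length(hydrophobic) == n_particles, sum(hydrophobic) >= 2)
  box <- make_box(rep(params$box_edge, 3))
  L <- params$box_edge
  set.seed(params$seed)
  # dispersed start with a soft-core-wide spacing
  pos <- .dispersed_centers(n_particles, box, min_sep = params$core_sigma)
  hh <- outer(hydrophobic, hydrophobic, "&")
  diag(hh) <- FALSE
  sig <- params$core_sigma; rc <- params$well_range; D <- params$well_depth
  noise_sd <- sqrt(2 * params$kT * params$dt / params$friction)
  max_disp <- 0
  frames <- list()
  for (step in seq_len(params$n_steps)) {
    dx <- outer(pos[, 1], pos[, 1], "-"); dx <- dx - L * round(dx / L)
    dy <- outer(pos[, 2], pos[, 2], "-"); dy <- dy - L * round(dy / L)
    dz <- outer(pos[, 3], pos[, 3], "-"); dz <- dz - L * round(dz / L)
    r <- sqrt(dx^2 + dy^2 + dz^2)
    diag(r) <- Inf
    # scalar radial force: positive pushes the pair apart
    f <- matrix(0, n_particles, n_particles)
    core <- r < sig
    f[core] <- f[core] + 2 * params$core_k * (sig - r[core])
    att <- hh & r < rc
    f[att] <- f[att] - 4 * D * r[att] / rc^2 * (1 - (r[att] / rc)^2)
    if (params$bias) {
      wl <- hh & r < params$wall$a
      f[wl] <- f[wl] + wall_force(r[wl], params$wall)
    }
    fac <- f / r
    Fx <- rowSums(fac * dx); Fy <- rowSums(fac * dy); Fz <- rowSums(fac * dz)
    drift <- cbind(Fx, Fy, Fz) * params$dt / params$friction
    dn <- sqrt(rowSums(drift^2))
    over <- dn > params$max_move
    if (any(over)) drift[over, ] <- drift[over, ] * params$max_move / dn[over]
    disp <- drift + matrix(rnorm(3 * n_particles, sd = noise_sd),
                           n_particles, 3)
    step_max <- max(abs(disp))
    if (step_max > L / 2)
      stop("time step too large: displacement ", signif(step_max, 3),
           " A exceeds half the box; reduce dt", call. = FALSE)
    max_disp <- max(max_disp, step_max)
    pos <- wrap_positions(pos + disp, box)
    if (step %% params$save_every == 0)
      frames[[length(frames) + 1]] <- pos
  }
  list(frames = frame_source(frames, box), hydrophobic = hydrophobic,
       params = params, max_step_displacement = max_disp)
}

#' Time-averaged aggregation fraction of a toy run
#'
#' Applies the lipophilic aggregation criterion (a neighbour below
#' `cutoff`, strict) to the hydrophobic particles over the post-burn-in
#' frames.
#'
#' @param run result of [toy_brownian()].
#' @param cutoff neighbour criterion, Å (default 7).
#' @param burn_in fraction of initial frames discarded (default 0.5).
#' @return Average fraction in `[0, 1]`.
#' @export
toy_aggregation_fraction <- function(run, cutoff = 7.0, burn_in = 0.5) {
  fs <- run$frames
  keep <- seq_len(fs$n_frames) > burn_in * fs$n_frames
  sub <- frame_source(fs$positions[keep], fs$boxes[keep])
  interaction_fraction(sub, which(run$hydrophobic), cutoff = cutoff)$average
}
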