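# Desk-scale steered-association simulator.
#
# A coarse ligand is pulled into a rigid coarse receptor by distance-
# dependent centroid-centroid forces (harmonic with zero rest length, force
# magnitude k * d) under overdamped Langevin dynamics. Units: Angstrom, ps,
# Da, kJ/mol. The conversion 1 kJ/mol = 100 Da A^2/ps^2 makes the unit
# system consistent, so the bead mobility is 100/(m * gamma) in
# A^2 mol/(kJ ps) and the diffusion constant is kB*T * mobility.

# Boltzmann constant in kJ/(mol K) and the kJ/mol -> Da A^2/ps^2 factor
.KB_KJ_MOL_K <- 0.00831446
.KJ_MOL_TO_INTERNAL <- 100

#' Distance-dependent centroid steering force
#'
#' Zero-rest-length harmonic between the mass-weighted centers of two atom
#' groups: U = 0.5 k d^2, pulling force magnitude k * d.
#'
#' @param k force constant in kJ/(mol Angstrom^2) (>= 0).
#' @param group_a mobile centroid `atom_group` (combined-topology indices).
#' @param group_b target centroid `atom_group`.
#' @param label descriptive label.
#' @return object of class `steering_force`.
#' @export
steering_force <- function(k, group_a, group_b, label = "") {
  if (k < 0) stop("steering force constant must be >= 0")
  structure(list(k = k, group_a = group_a, group_b = group_b, label = label),
            class = "steering_force")
}

#' Simulation parameters
#'
#' Defaults follow the usual steered-MD setup (300 K, friction 1/ps) with a
#' coarse-grained time step.
#'
#' @param dt_ps integration step in ps.
#' @param friction_per_ps Langevin friction coefficient in 1/ps (default 1).
#' @param temperature_K temperature in K (default 300).
#' @param n_steps number of integration steps.
#' @param record_stride record every this many steps.
#' @param seed RNG seed.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(dt_ps = 0.02, friction_per_ps = 1, temperature_K = 300,
                       n_steps = 3000, record_stride = 30, seed = 1) {
  if (dt_ps <= 0) stop("dt_ps must be > 0")
  if (record_stride < 1) stop("record_stride must be >= 1")
  if (temperature_K < 0) stop("temperature_K must be >= 0")
  structure(list(dt_ps = dt_ps, friction_per_ps = friction_per_ps,
                 temperature_K = temperature_K, n_steps = as.integer(n_steps),
                 record_stride = as.integer(record_stride),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Coarse receptor-ligand toy system
#'
#' The receptor is an immobile set of exclusion spheres; the ligand is a
#' small set of bonded beads. Indices in `centroid groups`, bonds and the
#' TS atom map refer to the combined topology (receptor atoms first, then
#' ligand beads).
#'
#' @param receptor `md_structure` of receptor atoms.
#' @param receptor_radii per-receptor-atom exclusion radii in Angstrom.
#' @param ligand `md_structure` of ligand beads (masses from the atom table).
#' @param ligand_radii per-bead radii in Angstrom.
#' @param bonds data.frame (i, j, r0, k) of ligand bead bonds in combined
#'   indices, rest lengths in Angstrom, spring constants in kJ/(mol A^2).
#' @param centroid_groups named list of `atom_group`s for steering forces.
#' @param ts_map `ts_atom_map` into the combined topology.
#' @param k_rep receptor-ligand repulsion constant in kJ/(mol A^2).
#' @param receptor_steric logical per receptor atom; FALSE marks pure
#'   steering target sites that exert no excluded-volume repulsion.
#' @return object of class `toy_system` with fields atoms (combined table),
#'   coords (combined start coordinates), mobile (logical per atom), radii,
#'   bonds, centroid_groups, ts_map, k_rep, steric.
#' @export
toy_system <- function(receptor, receptor_radii, ligand, ligand_radii,
                       bonds, centroid_groups, ts_map, k_rep = 50,
                       receptor_steric = NULL) {
  n_rec <- nrow(receptor$atoms)
  n_lig <- nrow(ligand$atoms)
  if (length(receptor_radii) != n_rec || length(ligand_radii) != n_lig)
    stop("radius vectors must match atom counts")
  if (any(receptor_radii <= 0) || any(ligand_radii <= 0))
    stop("exclusion radii must be > 0")
  if (is.null(receptor_steric)) receptor_steric <- rep(TRUE, n_rec)
  if (length(receptor_steric) != n_rec)
    stop("receptor_steric must match the receptor atom count")
  atoms <- rbind(receptor$atoms, ligand$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  coords <- rbind(receptor$coords, ligand$coords)
  structure(list(
    atoms = atoms, coords = coords,
    mobile = c(rep(FALSE, n_rec), rep(TRUE, n_lig)),
    radii = c(receptor_radii, ligand_radii),
    steric = c(receptor_steric, rep(TRUE, n_lig)),
    n_receptor = n_rec,
    bonds = bonds, centroid_groups = centroid_groups, ts_map = ts_map,
    k_rep = k_rep
  ), class = "toy_system")
}

#' Steering potential energy of one frame
#'
#' @param coords N x 3 combined coordinates.
#' @param force `steering_force`.
#' @param atoms combined atom table (for mass weighting).
#' @return energy in kJ/mol: 0.5 k d^2 over the centroid distance d.
#' @export
steering_energy <- function(coords, force, atoms) {
  ca <- center_of_mass(coords, force$group_a, atoms)
  cb <- center_of_mass(coords, force$group_b, atoms)
  0.5 * force$k * sum((ca - cb)^2)
}

#' Total per-atom forces on a toy system
#'
#' Sums (i) each steering force k*d, distributed over the mobile centroid
#' atoms by mass fraction (the equal-and-opposite term on the rigid
#' receptor is discarded); (ii) harmonic bond forces among ligand beads;
#' (iii) a purely repulsive receptor-ligand pair force
#' F = k_rep (sigma - r) for r < sigma, sigma = receptor exclusion radius +
#' bead radius.
#'
#' @param coords N x 3 combined coordinates.
#' @param system `toy_system`.
#' @param forces list of `steering_force`s.
#' @return N x 3 matrix of forces in kJ/(mol Angstrom); zero rows on
#'   receptor atoms.
#' @export
total_forces <- function(coords, system, forces) {
  n <- nrow(coords)
  F <- matrix(0, n, 3)
  m <- system$atoms$mass

  for (sf in forces) {
    ia <- .heavy_indices(sf$group_a)
    ib <- .heavy_indices(sf$group_b)
    ca <- center_of_mass(coords, ia, system$atoms)
    cb <- center_of_mass(coords, ib, system$atoms)
    pull <- sf$k * (cb - ca)          # force on centroid a toward b
    wa <- m[ia] / sum(m[ia])
    F[ia, ] <- F[ia, ] + outer(wa, pull)
    wb <- m[ib] / sum(m[ib])
    F[ib, ] <- F[ib, ] - outer(wb, pull)
  }

  b <- system$bonds
  if (!is.null(b) && nrow(b) > 0) {
    d <- coords[b$j, , drop = FALSE] - coords[b$i, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    fmag <- b$k * (r - b$r0) / pmax(r, 1e-12)
    fb <- d * fmag
    ai <- rowsum(fb, group = b$i)
    F[as.integer(rownames(ai)), ] <- F[as.integer(rownames(ai)), ] + ai
    aj <- rowsum(fb, group = b$j)
    F[as.integer(rownames(aj)), ] <- F[as.integer(rownames(aj)), ] - aj
  }

  mob <- which(system$mobile)
  rec <- which(!system$mobile & system$steric)
  if (length(rec) && length(mob)) {
    lp <- coords[mob, , drop = FALSE]
    rp <- coords[rec, , drop = FALSE]
    d2 <- outer(rowSums(lp^2), rowSums(rp^2), `+`) - 2 * lp %*% t(rp)
    sig <- outer(system$radii[mob], system$radii[rec], `+`)
    hit <- which(d2 < sig^2, arr.ind = TRUE)
    if (nrow(hit)) {
      r <- sqrt(pmax(d2[hit], 0))
      if (any(r == 0))
        stop("ligand bead exactly at a receptor atom center: direction undefined")
      i <- mob[hit[, 1]]; j <- rec[hit[, 2]]
      u <- (coords[i, , drop = FALSE] - coords[j, , drop = FALSE]) / r
      agg <- rowsum(u * (system$k_rep * (sig[hit] - r)), group = i)
      ids <- as.integer(rownames(agg))
      F[ids, ] <- F[ids, ] + agg
    }
  }

  F[!system$mobile, ] <- 0
  F
}

#' One overdamped Langevin step (Euler-Maruyama)
#'
#' x <- x + mobility * F * dt + sqrt(2 D dt) * xi, with per-bead mobility
#' 100/(m gamma) (kJ/mol force units) and D = kB T * mobility. Receptor
#' atoms never move; at T = 0 the noise term is exactly zero. Errors when
#' the deterministic displacement of any bead reaches the smallest
#' exclusion radius (time step too large).
#'
#' @param coords N x 3 combined coordinates.
#' @param system `toy_system`.
#' @param forces list of `steering_force`s.
#' @param params `sim_params`.
#' @return N x 3 coordinates after one step.
#' @export
step_overdamped <- function(coords, system, forces, params) {
  F <- total_forces(coords, system, forces)
  mob <- system$mobile
  m <- system$atoms$mass[mob]
  mobility <- .KJ_MOL_TO_INTERNAL / (m * params$friction_per_ps)  # A^2 mol/(kJ ps)
  drift <- F[mob, , drop = FALSE] * (mobility * params$dt_ps)
  maxdisp <- sqrt(max(rowSums(drift^2)))
  if (maxdisp >= min(system$radii[system$steric]))
    stop("deterministic displacement ", signif(maxdisp, 3),
         " A in one step reaches the smallest exclusion radius; reduce dt_ps")
  out <- coords
  if (params$temperature_K > 0) {
    D <- .KB_KJ_MOL_K * params$temperature_K * mobility   # A^2/ps
    noise <- matrix(stats::rnorm(3 * sum(mob)), ncol = 3) *
      sqrt(2 * D * params$dt_ps)
    out[mob, ] <- coords[mob, , drop = FALSE] + drift + noise
  } else {
    out[mob, ] <- coords[mob, , drop = FALSE] + drift
  }
  out
}

# Precompute everything the inner loop needs: the receptor is rigid, so
# receptor-side centroids, transposes and pair radii are loop invariants and
# the dynamics can be advanced on the small ligand coordinate block alone.
# The math is identical to step_overdamped(); tests assert the equivalence.
.prepare_fast_sim <- function(system, forces, params) {
  mob <- which(system$mobile)
  n_lig <- length(mob)
  m <- system$atoms$mass
  env <- new.env(parent = emptyenv())
  env$mob <- mob
  env$mobility <- .KJ_MOL_TO_INTERNAL / (m[mob] * params$friction_per_ps)
  env$noise_sd <- sqrt(2 * .KB_KJ_MOL_K * params$temperature_K *
                         env$mobility * params$dt_ps)
  env$dt <- params$dt_ps
  env$check_radius <- min(system$radii[system$steric])

  # steering: per force, the (fixed or mobile) sides resolved to local rows
  env$steer <- lapply(forces, function(sf) {
    ia <- .heavy_indices(sf$group_a); ib <- .heavy_indices(sf$group_b)
    list(k = sf$k,
         a_rows = match(ia, mob), a_w = m[ia] / sum(m[ia]),
         a_fixed = if (anyNA(match(ia, mob)))
           center_of_mass(system$coords, ia, system$atoms) else NULL,
         b_rows = match(ib, mob), b_w = m[ib] / sum(m[ib]),
         b_fixed = if (anyNA(match(ib, mob)))
           center_of_mass(system$coords, ib, system$atoms) else NULL)
  })

  b <- system$bonds
  if (!is.null(b) && nrow(b) > 0) {
    env$bond_i <- match(b$i, mob); env$bond_j <- match(b$j, mob)
    env$bond_r0 <- b$r0; env$bond_k <- b$k
    inc <- matrix(0, n_lig, nrow(b))
    for (r in seq_len(nrow(b))) {
      inc[env$bond_i[r], r] <- 1
      inc[env$bond_j[r], r] <- -1
    }
    env$bond_inc <- inc
  }

  rec <- which(!system$mobile & system$steric)
  env$rec_t <- t(system$coords[rec, , drop = FALSE])
  env$rec2 <- colSums(env$rec_t^2)
  env$sig <- outer(system$radii[mob], system$radii[rec], `+`)
  env$sig2 <- env$sig^2
  env$rec_coords <- system$coords[rec, , drop = FALSE]
  env$k_rep <- system$k_rep
  env
}

.fast_forces <- function(L, env) {
  F <- matrix(0, nrow(L), 3)
  for (sf in env$steer) {
    ca <- if (is.null(sf$a_fixed)) as.numeric(crossprod(L[sf$a_rows, , drop = FALSE], sf$a_w)) else sf$a_fixed
    cb <- if (is.null(sf$b_fixed)) as.numeric(crossprod(L[sf$b_rows, , drop = FALSE], sf$b_w)) else sf$b_fixed
    pull <- sf$k * (cb - ca)
    if (is.null(sf$a_fixed))
      F[sf$a_rows, ] <- F[sf$a_rows, ] + outer(sf$a_w, pull)
    if (is.null(sf$b_fixed))
      F[sf$b_rows, ] <- F[sf$b_rows, ] - outer(sf$b_w, pull)
  }
  if (!is.null(env$bond_inc)) {
    d <- L[env$bond_j, , drop = FALSE] - L[env$bond_i, , drop = FALSE]
    r <- sqrt(rowSums(d^2))
    fb <- d * (env$bond_k * (r - env$bond_r0) / pmax(r, 1e-12))
    F <- F + env$bond_inc %*% fb
  }
  d2 <- outer(rowSums(L^2), env$rec2, `+`) - 2 * L %*% env$rec_t
  hit <- which(d2 < env$sig2, arr.ind = TRUE)
  if (nrow(hit)) {
    r <- sqrt(pmax(d2[hit], 0))
    if (any(r == 0))
      stop("ligand bead exactly at a receptor atom center: direction undefined")
    i <- hit[, 1]
    u <- (L[i, , drop = FALSE] - env$rec_coords[hit[, 2], , drop = FALSE]) / r
    agg <- rowsum(u * (env$k_rep * (env$sig[hit] - r)), group = i)
    ids <- as.integer(rownames(agg))
    F[ids, ] <- F[ids, ] + agg
  }
  F
}

#' Run one steered-association replicate
#'
#' Seeds the RNG from `params$seed`, integrates `n_steps` overdamped steps
#' and records the initial frame plus every `record_stride`-th step.
#'
#' @param system `toy_system`.
#' @param forces list of `steering_force`s.
#' @param params `sim_params`.
#' @return `md_trajectory` over the combined topology;
#'   frame_interval_ps = dt_ps * record_stride.
#' @export
run_replicate <- function(system, forces, params) {
  env <- .prepare_fast_sim(system, forces, params)
  .with_seed(params$seed, {
    coords <- system$coords
    L <- coords[env$mob, , drop = FALSE]
    frames <- vector("list", params$n_steps %/% params$record_stride + 1L)
    frames[[1L]] <- coords
    fi <- 1L
    for (s in seq_len(params$n_steps)) {
      F <- .fast_forces(L, env)
      drift <- F * (env$mobility * env$dt)
      maxdisp <- sqrt(max(rowSums(drift^2)))
      if (maxdisp >= env$check_radius)
        stop("deterministic displacement ", signif(maxdisp, 3),
             " A in one step reaches the smallest exclusion radius; reduce dt_ps")
      L <- L + drift
      if (env$noise_sd[1] > 0)
        L <- L + matrix(stats::rnorm(3 * nrow(L)), ncol = 3) * env$noise_sd
      if (s %% params$record_stride == 0L) {
        fi <- fi + 1L
        coords[env$mob, ] <- L
        frames[[fi]] <- coords
      }
    }
    md_trajectory(system$atoms, frames[seq_len(fi)],
                  frame_interval_ps = params$dt_ps * params$record_stride)
  })
}

#' Run a replicate ensemble
#'
#' Replicate i runs with seed `base_seed + i`, giving independent,
#' individually reproducible noise streams.
#'
#' @param system `toy_system`.
#' @param forces list of `steering_force`s.
#' @param params `sim_params` (its seed field is ignored).
#' @param n_replicates number of replicates (>= 1).
#' @param base_seed ensemble base seed.
#' @return list of `md_trajectory`.
#' @export
run_ensemble <- function(system, forces, params, n_replicates, base_seed) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  lapply(seq_len(n_replicates), function(i) {
    p <- params
    p$seed <- as.integer(base_seed + i)
    run_replicate(system, forces, p)
  })
}
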