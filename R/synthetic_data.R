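# Synthetic-structure generators with analytic ground truth.
#
# These generators give every pipeline stage an input whose correct answer
# is known by construction: four-atom SN2 geometries with prescribed
# internal coordinates, hollow atom shells enclosing cavities of known
# volume, trajectories with prescribed contact fractions, and coarse
# receptor-ligand systems with open vs. occluded binding pockets.

# seeded proper random rotation (det = +1) via QR of a Gaussian matrix
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

.unit <- function(v) v / sqrt(sum(v^2))

# quasi-uniform points on a sphere of radius r (Fibonacci lattice) with
# approximate nearest-neighbor spacing `spacing`
.fibonacci_sphere <- function(r, spacing) {
  n <- max(8L, ceiling(4 * pi * r^2 / spacing^2))
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(r * s * cos(phi), r * s * sin(phi), r * z)
}

#' Four-atom SN2 geometry with prescribed internal coordinates
#'
#' Places the lysine C-delta at the origin, N-epsilon at 1.5 Angstrom, the
#' cofactor methyl carbon at distance `d` from N-epsilon under the requested
#' attack angle, and the sulfur 1.8 Angstrom from the methyl carbon under
#' the requested linearity angle, then applies a seeded random rigid
#' transform. Measuring the three internal coordinates on the result
#' recovers the inputs to machine precision.
#'
#' @param d N-epsilon to methyl-C distance in Angstrom (> 0).
#' @param attack_angle angle C-delta -- N-epsilon -- methyl-C in degrees,
#'   in (0, 180].
#' @param linearity_angle angle N-epsilon -- methyl-C -- S in degrees, in
#'   (0, 180].
#' @param rigid_seed seed for the random rigid transform (NULL: keep the
#'   canonical placement).
#' @return `md_structure` of 4 atoms (CD, NZ, CE, SD) with attribute
#'   `ts_map`, the matching [ts_atom_map()].
#' @export
make_sn2_geometry <- function(d, attack_angle, linearity_angle,
                              rigid_seed = NULL) {
  if (d <= 0) stop("d must be > 0")
  if (attack_angle <= 0 || attack_angle > 180 ||
      linearity_angle <= 0 || linearity_angle > 180)
    stop("angles must be in (0, 180] degrees")
  a <- attack_angle * pi / 180
  l <- linearity_angle * pi / 180
  cd <- c(0, 0, 0)
  ne <- c(1.5, 0, 0)
  # direction NE -> CD is (-1, 0, 0); methyl C in the xy-plane
  cm <- ne + d * (cos(a) * c(-1, 0, 0) + sin(a) * c(0, 1, 0))
  u <- .unit(ne - cm)
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  w <- .unit(ref - sum(ref * u) * u)
  sd_ <- cm + 1.8 * (cos(l) * u + sin(l) * w)
  xyz <- rbind(cd, ne, cm, sd_)
  if (!is.null(rigid_seed)) {
    xyz <- .with_seed(rigid_seed, {
      R <- .random_rotation()
      t <- stats::runif(3, -20, 20)
      sweep(xyz %*% t(R), 2, t, `+`)
    })
  }
  atoms <- make_atoms(name = c("CD", "NZ", "CE", "SD"),
                      element = c("C", "N", "C", "S"),
                      resid = c(36L, 36L, 200L, 200L),
                      resname = c("LYS", "LYS", "SAM", "SAM"))
  s <- md_structure(atoms, xyz)
  attr(s, "ts_map") <- ts_atom_map(n_epsilon = 2, c_delta = 1,
                                   methyl_c = 3, sulfur = 4)
  s
}

#' Hollow spherical-shell receptor with analytic cavity volume
#'
#' Atoms cover concentric spherical layers between `cavity_radius` and
#' `cavity_radius + shell_thickness` around `center`. The analytic
#' reference is the volume of the ball accessible after proximity
#' inflation: radius `min(cavity_radius - inflation, inclusion_radius)`.
#'
#' @param cavity_radius inner cavity radius in Angstrom.
#' @param shell_thickness radial shell thickness in Angstrom.
#' @param atom_spacing approximate atom spacing on each layer in Angstrom
#'   (must be < shell_thickness + layer gap to leave no holes).
#' @param element element symbol of the shell atoms.
#' @param center cavity center.
#' @param inflation proximity inflation used for the analytic reference
#'   (distance_cut in center mode, vdw + distance_cut in vdw mode).
#' @param inclusion_radius radius of the inclusion sphere the grid will use.
#' @return list with `structure` (`md_structure`) and `analytic_volume`
#'   (cubic Angstrom).
#' @export
make_pocket_shell <- function(cavity_radius, shell_thickness = 0.3,
                              atom_spacing = 0.3, element = "C",
                              center = c(0, 0, 0), inflation = 0.4,
                              inclusion_radius = 3) {
  stopifnot(cavity_radius > 0, shell_thickness > 0, atom_spacing > 0)
  radii <- seq(cavity_radius, cavity_radius + shell_thickness,
               by = atom_spacing)
  xyz <- do.call(rbind, lapply(radii, .fibonacci_sphere, spacing = atom_spacing))
  xyz <- sweep(xyz, 2, center, `+`)
  atoms <- make_atoms(name = rep(element, nrow(xyz)),
                      element = rep(element, nrow(xyz)), resid = 1L,
                      resname = "SHL")
  r_acc <- min(cavity_radius - inflation, inclusion_radius)
  vol <- if (r_acc > 0) 4 / 3 * pi * r_acc^3 else 0
  list(structure = md_structure(atoms, xyz), analytic_volume = vol)
}

#' Two-residue trajectory with a prescribed contact fraction
#'
#' Two single-atom residues separated by `d_in` in exactly
#' `round(n_frames * fraction)` frames and `d_out` otherwise, in seeded
#' shuffled order.
#'
#' @param n_frames number of frames.
#' @param fraction target contact fraction in [0, 1].
#' @param d_in in-contact separation (below the intended cutoff).
#' @param d_out out-of-contact separation (above the cutoff).
#' @param seed shuffle seed.
#' @return `md_trajectory` of two atoms (resid 1 and 2).
#' @export
make_contact_trajectory <- function(n_frames, fraction, d_in = 3, d_out = 8,
                                    seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1, d_in < d_out, n_frames >= 1)
  n_in <- round(n_frames * fraction)
  sep <- c(rep(d_in, n_in), rep(d_out, n_frames - n_in))
  sep <- .with_seed(seed, sample(sep))
  atoms <- make_atoms(name = c("CA", "CA"), element = c("C", "C"),
                      resid = c(1L, 2L), resname = c("ALA", "GLY"))
  frames <- lapply(sep, function(s) rbind(c(0, 0, 0), c(s, 0, 0)))
  md_trajectory(atoms, frames)
}

#' Trajectory alternating open and collapsed cavity shells
#'
#' Frames share one shell topology; "open" frames use the full cavity
#' radius (volume in the large band) and "collapsed" frames shrink all
#' atoms radially (volume in the low band). Frame order is a seeded
#' shuffle.
#'
#' @param open_frames,collapsed_frames frame counts per state.
#' @param seed shuffle seed.
#' @param open_radius,collapsed_radius cavity radii in Angstrom.
#' @param atom_spacing shell atom spacing in Angstrom.
#' @param inflation,inclusion_radius as in [make_pocket_shell()].
#' @return list with `trajectory`, logical `open` per frame, and the two
#'   analytic volumes `volume_open`, `volume_collapsed`.
#' @export
make_volume_trajectory <- function(open_frames, collapsed_frames, seed = 1,
                                   open_radius = 3.2, collapsed_radius = 1.9,
                                   atom_spacing = 0.3, inflation = 0.4,
                                   inclusion_radius = 3) {
  stopifnot(open_frames >= 0, collapsed_frames >= 0,
            open_frames + collapsed_frames >= 1)
  shell <- make_pocket_shell(open_radius, shell_thickness = 0.3,
                             atom_spacing = atom_spacing,
                             inflation = inflation,
                             inclusion_radius = inclusion_radius)
  base <- shell$structure$coords
  is_open <- c(rep(TRUE, open_frames), rep(FALSE, collapsed_frames))
  is_open <- .with_seed(seed, sample(is_open))
  scale <- collapsed_radius / open_radius
  frames <- lapply(is_open, function(o) if (o) base else base * scale)
  r_open <- min(open_radius - inflation, inclusion_radius)
  r_coll <- min(collapsed_radius - inflation, inclusion_radius)
  list(trajectory = md_trajectory(shell$structure$atoms, frames),
       open = is_open,
       volume_open = 4 / 3 * pi * max(0, r_open)^3,
       volume_collapsed = 4 / 3 * pi * max(0, r_coll)^3)
}

#' Coarse receptor-ligand association system
#'
#' Builds a rigid spherical pocket (radius 6 Angstrom) with a mouth along
#' +z, a lysine-like N-epsilon / C-delta pair at the pocket center, two
#' anchor triads for the secondary steering forces, and an 8-bead cofactor
#' ligand (methyl carbon, sulfur, amino-acid and adenine triads) placed
#' with its center of mass `start_distance` along +z from the pocket
#' center. The occluded variant seals the mouth with wide gate spheres so
#' the ligand cannot reach the catalytic site.
#'
#' The returned system carries the three standard steering forces in
#' `$forces`: 0.2 kJ/(mol A^2) methyl-to-N-epsilon, 0.1 adenine-to-anchor,
#' 0.05 amino-to-anchor.
#'
#' @param pocket "open" or "occluded".
#' @param start_distance initial ligand COM distance in Angstrom
#'   (default 27).
#' @return `toy_system` with an extra `forces` field.
#' @export
make_toy_association_system <- function(pocket = c("open", "occluded"),
                                        start_distance = 27) {
  pocket <- match.arg(pocket)
  if (start_distance <= 8) stop("start_distance must exceed the pocket size")
  R <- 6
  sphere <- .fibonacci_sphere(R, spacing = 1.2)
  mouth <- sphere[, 3] > R * cos(55 * pi / 180)
  wall <- sphere[!mouth, , drop = FALSE]
  # occlusion: one wide gate sphere whose surface swallows the mouth rim,
  # sealing the aperture with a single smooth obstacle
  gate <- matrix(c(0, 0, 4.0), 1, 3)

  lig_local <- rbind(
    CM = c(0, 0, 0), SD = c(0, 0, 1.8),
    CB = c(0.8, 0, 2.7), CA = c(1.4, 0, 3.7), N0 = c(1.9, 0, 4.6),
    N1 = c(-0.8, 0, 2.7), C2 = c(-1.4, 0, 3.7), N3 = c(-1.9, 0, 4.6))
  # docked rest pose: methyl C in contact on top of NZ (1.5 + 1.3 Angstrom)
  rest <- sweep(lig_local, 2, c(0, 0, 2.8), `+`)

  u109 <- c(sin(109 * pi / 180), 0, cos(109 * pi / 180))
  # anchor triads sit at the docked resting positions of the ligand triads,
  # so the weaker guide forces vanish in the bound pose and exert no net
  # torque there
  special <- rbind(c(0, 0, 0),            # NZ, catalytic N-epsilon
                   1.5 * u109,            # CD at 109 deg from the mouth axis
                   rest[c("N1", "C2", "N3"), ],   # 1202 N, CA, C
                   rest[c("CB", "CA", "N0"), ])   # 1149 CA, C, O
  rec_xyz <- rbind(wall, special)
  rec_names <- c(rep("W", nrow(wall)), "NZ", "CD", "N", "CA", "C", "CA", "C", "O")
  rec_el <- c(rep("C", nrow(wall)), "N", "C", "N", "C", "C", "C", "C", "O")
  rec_resid <- c(rep(1L, nrow(wall)), 36L, 36L, 1202L, 1202L, 1202L,
                 1149L, 1149L, 1149L)
  rec_resname <- c(rep("WAL", nrow(wall)), "LYS", "LYS", "LEU", "LEU", "LEU",
                   "PHE", "PHE", "PHE")
  rec_radii <- c(rep(1.4, nrow(wall)), 1.5, 0.9, rep(0.9, 6))
  rec_steric <- c(rep(TRUE, nrow(wall)), TRUE, TRUE, rep(FALSE, 6))
  if (pocket == "occluded") {
    rec_xyz <- rbind(rec_xyz, gate)
    rec_names <- c(rec_names, rep("G", nrow(gate)))
    rec_el <- c(rec_el, rep("C", nrow(gate)))
    rec_resid <- c(rec_resid, rep(2L, nrow(gate)))
    rec_resname <- c(rec_resname, rep("GAT", nrow(gate)))
    rec_radii <- c(rec_radii, rep(5.0, nrow(gate)))
    rec_steric <- c(rec_steric, rep(TRUE, nrow(gate)))
  }
  receptor <- md_structure(
    make_atoms(rec_names, rec_el, resid = rec_resid, resname = rec_resname,
               chain = "R"),
    rec_xyz)

  lig_xyz <- sweep(lig_local, 2, colMeans(lig_local))
  lig_xyz <- sweep(lig_xyz, 2, c(0, 0, start_distance), `+`)
  lig_atoms <- make_atoms(rownames(lig_local),
                          element = c("C", "S", "C", "C", "N", "N", "C", "N"),
                          resid = 500L, resname = "SAM", chain = "L")
  lig_atoms$mass <- rep(150, nrow(lig_atoms))   # coarse beads, not elements
  ligand <- md_structure(lig_atoms, lig_xyz)

  n_rec <- nrow(receptor$atoms)
  li <- function(nm) n_rec + match(nm, rownames(lig_local))
  ri_nz <- which(rec_names == "NZ")
  ri_cd <- which(rec_names == "CD")
  ri_1202 <- which(rec_resid == 1202L)
  ri_1149 <- which(rec_resid == 1149L)

  bond_pairs <- rbind(c("CM", "SD"), c("SD", "CB"), c("CB", "CA"),
                      c("CA", "N0"), c("SD", "N1"), c("N1", "C2"),
                      c("C2", "N3"), c("CM", "CB"), c("CM", "N1"),
                      c("CB", "N1"))
  bi <- vapply(bond_pairs[, 1], li, integer(1))
  bj <- vapply(bond_pairs[, 2], li, integer(1))
  full0 <- rbind(receptor$coords, ligand$coords)
  r0 <- sqrt(rowSums((full0[bi, , drop = FALSE] - full0[bj, , drop = FALSE])^2))
  bonds <- data.frame(i = bi, j = bj, r0 = r0, k = 10)

  groups <- list(
    lig_methyl = atom_group(li("CM"), "ligand methyl C"),
    lig_adenine = atom_group(sort(li(c("N1", "C2", "N3"))), "ligand adenine triad"),
    lig_amino = atom_group(sort(li(c("N0", "CA", "CB"))), "ligand amino-acid triad"),
    rec_nz = atom_group(ri_nz, "receptor N-epsilon"),
    rec_1202 = atom_group(ri_1202, "receptor 1202 triad"),
    rec_1149 = atom_group(ri_1149, "receptor 1149 triad"))

  sys <- toy_system(
    receptor = receptor, receptor_radii = rec_radii,
    ligand = ligand, ligand_radii = rep(1.3, 8),
    bonds = bonds, centroid_groups = groups,
    ts_map = ts_atom_map(n_epsilon = ri_nz, c_delta = ri_cd,
                         methyl_c = li("CM"), sulfur = li("SD")),
    k_rep = 6, receptor_steric = rec_steric)
  sys$forces <- list(
    steering_force(0.2, groups$lig_methyl, groups$rec_nz, "force1 methyl->NE"),
    steering_force(0.1, groups$lig_adenine, groups$rec_1202, "force2 adenine->1202"),
    steering_force(0.05, groups$lig_amino, groups$rec_1149, "force3 amino->1149"))
  sys$pocket <- pocket
  sys
}

#' Materialize the synthetic fixtures on disk
#'
#' Writes the standard fixture set (SN2 geometry, pocket shell, contact
#' trajectory, toy association systems) as PDB files plus a manifest TSV of
#' their ground-truth values.
#'
#' @param dir output directory (created if needed).
#' @param seed seed for the seeded fixtures.
#' @return invisibly, the manifest data.frame.
#' @export
write_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  add <- function(file, quantity, value)
    rows[[length(rows) + 1L]] <<- data.frame(file = file, quantity = quantity,
                                             value = value)

  sn2 <- make_sn2_geometry(3.5, 109, 180, rigid_seed = seed)
  write_pdb(sn2, file.path(dir, "sn2_geometry.pdb"))
  add("sn2_geometry.pdb", "d_NE_CM_A", 3.5)
  add("sn2_geometry.pdb", "attack_angle_deg", 109)
  add("sn2_geometry.pdb", "linearity_angle_deg", 180)

  shell <- make_pocket_shell(3.0)
  write_pdb(shell$structure, file.path(dir, "pocket_shell.pdb"))
  add("pocket_shell.pdb", "analytic_cavity_volume_A3", shell$analytic_volume)

  ct <- make_contact_trajectory(100, 0.15, seed = seed)
  write_pdb(ct, file.path(dir, "contact_trajectory.pdb"))
  add("contact_trajectory.pdb", "contact_fraction", 0.15)

  for (p in c("open", "occluded")) {
    sys <- make_toy_association_system(p)
    write_pdb(md_structure(sys$atoms, sys$coords),
              file.path(dir, paste0("toy_system_", p, ".pdb")))
    add(paste0("toy_system_", p, ".pdb"), "start_com_distance_A", 27)
  }

  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
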