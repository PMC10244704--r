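# Geometric detection of SN2 transition-state-like cofactor docking.
#
# A frame counts as a TS-like docking event when the methyl-transfer
# geometry known from SN2 chemistry is realized: the attacking lysine
# N-epsilon close to the transferred methyl carbon, an approach angle near
# tetrahedral at the nitrogen, and near-linear N...C-S alignment through
# the leaving sulfur.

#' Transition-state geometric criteria
#'
#' @param d_max maximum N-epsilon to methyl-C distance in Angstrom (strict
#'   upper bound, default 4).
#' @param attack_angle_center,attack_angle_tol attack-angle window in
#'   degrees (default 109 +/- 30, inclusive).
#' @param linearity_center,linearity_tol near-linearity window in degrees
#'   (default 180 +/- 30, inclusive). Interior angles are folded to
#'   [0, 180], so this window is equivalent to angle >= 150.
#' @return object of class `ts_criteria`.
#' @export
ts_criteria <- function(d_max = 4, attack_angle_center = 109,
                        attack_angle_tol = 30, linearity_center = 180,
                        linearity_tol = 30) {
  if (d_max <= 0) stop("d_max must be > 0")
  if (attack_angle_tol <= 0 || attack_angle_tol >= 90 ||
      linearity_tol <= 0 || linearity_tol >= 90)
    stop("angle tolerances must be in (0, 90)")
  structure(list(d_max = d_max,
                 attack_angle_center = attack_angle_center,
                 attack_angle_tol = attack_angle_tol,
                 linearity_center = linearity_center,
                 linearity_tol = linearity_tol),
            class = "ts_criteria")
}

#' Map of the four catalytic atoms
#'
#' @param n_epsilon index of the substrate lysine N-epsilon.
#' @param c_delta index of the lysine C-delta.
#' @param methyl_c index of the cofactor methyl carbon.
#' @param sulfur index of the cofactor sulfur.
#' @return object of class `ts_atom_map`.
#' @export
ts_atom_map <- function(n_epsilon, c_delta, methyl_c, sulfur) {
  idx <- c(n_epsilon, c_delta, methyl_c, sulfur)
  if (length(unique(idx)) != 4L) stop("the four catalytic atom indices must be distinct")
  structure(list(n_epsilon = as.integer(n_epsilon),
                 c_delta = as.integer(c_delta),
                 methyl_c = as.integer(methyl_c),
                 sulfur = as.integer(sulfur)),
            class = "ts_atom_map")
}

#' Euclidean distance between two atoms in a frame
#'
#' @param coords N x 3 frame coordinates.
#' @param i,j atom indices.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(coords, i, j) {
  sqrt(sum((coords[i, ] - coords[j, ])^2))
}

#' Interior angle at the middle atom, in degrees
#'
#' Returns the folded angle a-b-c in [0, 180]. Computed as
#' atan2(|u x v|, u . v), which is numerically equivalent to the arccosine
#' of the clamped normalized dot product but stays well-conditioned for
#' near-collinear geometries (the linearity criterion lives near 180).
#'
#' @param coords N x 3 frame coordinates.
#' @param a,b,c atom indices; the angle is measured at `b`.
#' @return angle in degrees.
#' @export
angle_deg <- function(coords, a, b, c) {
  u <- coords[a, ] - coords[b, ]
  v <- coords[c, ] - coords[b, ]
  if (sum(u^2) == 0 || sum(v^2) == 0)
    stop("zero-length arm in angle computation")
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
}

#' Classify one frame against the TS criteria
#'
#' Evaluates the N-epsilon to methyl-C distance (strict `< d_max`), the
#' attack angle C-delta -- N-epsilon -- methyl-C and the linearity angle
#' N-epsilon -- methyl-C -- S (both windows inclusive).
#'
#' @param coords N x 3 frame coordinates.
#' @param atom_map `ts_atom_map`.
#' @param criteria `ts_criteria`.
#' @param frame_index frame index stored in the result.
#' @return list (class `ts_frame_result`) with fields frame_index,
#'   distance, attack_angle, linearity_angle, passed.
#' @export
classify_ts_frame <- function(coords, atom_map, criteria = ts_criteria(),
                              frame_index = 1L) {
  d <- atom_distance(coords, atom_map$n_epsilon, atom_map$methyl_c)
  attack <- angle_deg(coords, atom_map$c_delta, atom_map$n_epsilon,
                      atom_map$methyl_c)
  linearity <- angle_deg(coords, atom_map$n_epsilon, atom_map$methyl_c,
                         atom_map$sulfur)
  passed <- (d < criteria$d_max) &&
    (abs(attack - criteria$attack_angle_center) <= criteria$attack_angle_tol) &&
    (abs(linearity - criteria$linearity_center) <= criteria$linearity_tol)
  structure(list(frame_index = frame_index, distance = d,
                 attack_angle = attack, linearity_angle = linearity,
                 passed = passed),
            class = "ts_frame_result")
}

#' Scan a trajectory for TS-like docking events
#'
#' Classifies every recorded frame and aggregates the replicate outcome: a
#' replicate is successful when at least one frame passes.
#'
#' @param trajectory `md_trajectory`.
#' @param atom_map `ts_atom_map`.
#' @param criteria `ts_criteria`.
#' @param replicate_id identifier stored in the outcome.
#' @return list with `frames` (data.frame: frame_index, distance,
#'   attack_angle, linearity_angle, passed) and `outcome` (list:
#'   replicate_id, successful, first_passing_frame, n_passing_frames).
#' @export
scan_trajectory <- function(trajectory, atom_map, criteria = ts_criteria(),
                            replicate_id = 1L) {
  res <- lapply(seq_along(trajectory$frames), function(f)
    classify_ts_frame(trajectory$frames[[f]], atom_map, criteria, f))
  frames <- data.frame(
    frame_index = vapply(res, `[[`, integer(1), "frame_index"),
    distance = vapply(res, `[[`, numeric(1), "distance"),
    attack_angle = vapply(res, `[[`, numeric(1), "attack_angle"),
    linearity_angle = vapply(res, `[[`, numeric(1), "linearity_angle"),
    passed = vapply(res, `[[`, logical(1), "passed")
  )
  npass <- sum(frames$passed)
  outcome <- list(
    replicate_id = replicate_id,
    successful = npass >= 1L,
    first_passing_frame = if (npass) frames$frame_index[which(frames$passed)[1]] else NA_integer_,
    n_passing_frames = npass
  )
  list(frames = frames, outcome = outcome)
}

#' Count successful replicates
#'
#' @param outcomes list of replicate outcomes (as returned in
#'   `scan_trajectory()$outcome`).
#' @return integer number of replicates with at least one passing frame.
#' @export
count_successes <- function(outcomes) {
  if (length(outcomes) == 0L) return(0L)
  sum(vapply(outcomes, function(o) isTRUE(o$successful), logical(1)))
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation R (det = +1) and translation t minimizing the
#' RMSD between `mobile[fit_group, ]` and `reference[fit_group, ]`, and
#' applies the transform to all mobile atoms.
#'
#' @param mobile,reference N x 3 coordinate matrices over the same atom
#'   ordering.
#' @param fit_group `atom_group` or index vector (>= 3 non-collinear atoms).
#' @return list with `rotation` (3 x 3), `translation` (length 3) and
#'   `fitted` (N x 3 transformed mobile coordinates).
#' @export
superpose_kabsch <- function(mobile, reference, fit_group) {
  idx <- if (inherits(fit_group, "atom_group")) fit_group$indices else as.integer(fit_group)
  if (length(idx) < 3L) stop("fit group must contain at least 3 atoms")
  xm <- mobile[idx, , drop = FALSE]
  xr <- reference[idx, , drop = FALSE]
  cm <- colMeans(xm); cr <- colMeans(xr)
  xm <- sweep(xm, 2, cm); xr <- sweep(xr, 2, cr)
  H <- crossprod(xm, xr)
  sv <- svd(H)
  # collinear fit groups leave the rotation about the common axis undefined
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("fit group is (near-)collinear; superposition is ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- sweep(mobile, 2, cm) %*% t(R)
  fitted <- sweep(fitted, 2, cr, `+`)
  tr <- as.numeric(cr - R %*% cm)
  list(rotation = R, translation = tr, fitted = fitted)
}

#' RMSD of a docked ligand pose against a bound reference
#'
#' Superposes the frame onto the reference over `fit_group` (typically
#' receptor C-alpha atoms), then reports the coordinate RMSD over
#' `ligand_group` (typically cofactor heavy atoms).
#'
#' @param frame N x 3 coordinates of the docked frame.
#' @param reference `md_structure` or N x 3 matrix of the bound reference.
#' @param fit_group,ligand_group `atom_group`s or index vectors valid in
#'   both topologies, same size and order.
#' @return RMSD in Angstrom.
#' @export
docking_rmsd <- function(frame, reference, fit_group, ligand_group) {
  ref <- if (inherits(reference, "md_structure")) reference$coords else reference
  lig <- if (inherits(ligand_group, "atom_group")) ligand_group$indices else as.integer(ligand_group)
  if (max(lig) > nrow(frame) || max(lig) > nrow(ref))
    stop("ligand group exceeds topology size")
  if (nrow(frame) != nrow(ref))
    stop("frame and reference topologies differ in size")
  fitted <- superpose_kabsch(frame, ref, fit_group)$fitted
  diff <- fitted[lig, , drop = FALSE] - ref[lig, , drop = FALSE]
  sqrt(mean(rowSums(diff^2)))
}
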