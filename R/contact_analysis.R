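# Heavy-atom residue contact detection and per-replicate occupancy.
#
# Two residues are in contact in a frame when any pair of heavy atoms, one
# from each group, is closer than the cutoff (strictly below 4.5 Angstrom
# by default).

#' Contact specification
#'
#' @param group_a,group_b disjoint `atom_group`s of heavy atoms (or named
#'   subsets, e.g. a hydroxyl oxygen vs. a backbone nitrogen).
#' @param cutoff contact cutoff in Angstrom (default 4.5, strict).
#' @return object of class `contact_spec`.
#' @export
contact_spec <- function(group_a, group_b, cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  ia <- .heavy_indices(group_a); ib <- .heavy_indices(group_b)
  if (length(intersect(ia, ib)) > 0L) stop("contact groups must be disjoint")
  structure(list(group_a = ia, group_b = ib, cutoff = cutoff),
            class = "contact_spec")
}

#' Is a frame in contact?
#'
#' @param coords N x 3 frame coordinates (or `md_structure`).
#' @param spec `contact_spec`.
#' @return list with `in_contact` (TRUE iff the minimum pair distance is
#'   strictly below the cutoff) and `min_distance` in Angstrom.
#' @export
frame_in_contact <- function(coords, spec) {
  coords <- .frame_coords(coords)
  a <- coords[spec$group_a, , drop = FALSE]
  b <- coords[spec$group_b, , drop = FALSE]
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  dmin <- sqrt(max(0, min(d2)))
  list(in_contact = dmin < spec$cutoff, min_distance = dmin)
}

#' Per-frame contact series over a trajectory
#'
#' @param trajectory `md_trajectory`.
#' @param spec `contact_spec`.
#' @param replicate_id identifier stored in the series.
#' @return list (class `contact_series`) with `present` (logical per frame),
#'   `min_distance` (numeric per frame), spec, replicate_id.
#' @export
contact_series <- function(trajectory, spec, replicate_id = 1L) {
  res <- lapply(trajectory$frames, frame_in_contact, spec = spec)
  structure(list(
    present = vapply(res, `[[`, logical(1), "in_contact"),
    min_distance = vapply(res, `[[`, numeric(1), "min_distance"),
    spec = spec, replicate_id = replicate_id
  ), class = "contact_series")
}

#' Fraction of frames in contact
#'
#' @param trajectory `md_trajectory` or a `contact_series`.
#' @param spec `contact_spec` (ignored when a series is given).
#' @return occupancy fraction in [0, 1].
#' @export
contact_fraction <- function(trajectory, spec = NULL) {
  if (inherits(trajectory, "contact_series")) return(mean(trajectory$present))
  mean(contact_series(trajectory, spec)$present)
}

#' Summarize contact occupancy across replicates
#'
#' The per-replicate fraction (not the pooled frame count) is the
#' statistical unit; the mean is the unweighted arithmetic mean of the
#' replicate fractions.
#'
#' @param series_list list of `contact_series` (or a numeric vector of
#'   per-replicate fractions).
#' @return list (class `contact_summary`) with fractions, mean,
#'   n_replicates.
#' @export
summarize_replicates <- function(series_list) {
  if (is.numeric(series_list)) {
    fr <- series_list
  } else {
    if (length(series_list) < 1L) stop("need at least one replicate series")
    fr <- vapply(series_list, function(s) mean(s$present), numeric(1))
  }
  if (any(fr < 0 | fr > 1)) stop("occupancy fractions must be in [0, 1]")
  structure(list(fractions = fr, mean = mean(fr),
                 n_replicates = length(fr)),
            class = "contact_summary")
}
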