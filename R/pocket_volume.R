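# Grid-based active-site pocket volumetrics.
#
# The pocket volume of a frame is measured POVME-style: an axis-aligned
# lattice seeded inside user-defined inclusion spheres is pruned by
# receptor proximity, optionally restricted to the receptor convex hull,
# cleaned by a contiguity filter, and the surviving point count times the
# voxel volume is reported in cubic Angstrom.

.default_vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Inclusion sphere for pocket-grid seeding
#'
#' @param center length-3 numeric center (Angstrom).
#' @param radius sphere radius in Angstrom (default 3).
#' @return object of class `inclusion_sphere`.
#' @export
inclusion_sphere <- function(center, radius = 3) {
  if (radius <= 0) stop("inclusion sphere radius must be > 0")
  structure(list(center = as.numeric(center), radius = radius),
            class = "inclusion_sphere")
}

#' Pocket-grid configuration
#'
#' @param spacing lattice spacing in Angstrom (default 0.4).
#' @param distance_cut proximity cut in Angstrom (default 0.4).
#' @param contiguity_criterion minimum 26-neighborhood neighbor count a grid
#'   point needs to survive (default 3).
#' @param convex_hull_exclusion drop points outside the receptor heavy-atom
#'   convex hull (default TRUE).
#' @param proximity_mode "vdw" (default): a point is removed when within
#'   `vdw_radius + distance_cut` of a heavy atom; "center": removed when
#'   within `distance_cut` of an atom center.
#' @param vdw_radii named element -> radius table used in vdw mode.
#' @param inclusion list of [inclusion_sphere()]s.
#' @return object of class `grid_config`.
#' @export
grid_config <- function(spacing = 0.4, distance_cut = 0.4,
                        contiguity_criterion = 3,
                        convex_hull_exclusion = TRUE,
                        proximity_mode = c("vdw", "center"),
                        vdw_radii = .default_vdw,
                        inclusion = list(inclusion_sphere(c(0, 0, 0)))) {
  proximity_mode <- match.arg(proximity_mode)
  if (spacing <= 0) stop("spacing must be > 0")
  if (distance_cut < 0) stop("distance_cut must be >= 0")
  if (contiguity_criterion < 0 || contiguity_criterion > 26)
    stop("contiguity_criterion must be in [0, 26]")
  if (inherits(inclusion, "inclusion_sphere")) inclusion <- list(inclusion)
  structure(list(spacing = spacing, distance_cut = distance_cut,
                 contiguity_criterion = as.integer(contiguity_criterion),
                 convex_hull_exclusion = convex_hull_exclusion,
                 proximity_mode = proximity_mode, vdw_radii = vdw_radii,
                 inclusion = inclusion),
            class = "grid_config")
}

# Integer lattice coordinates of a point set relative to the grid anchor
# (the first inclusion-sphere center).
.lattice_ijk <- function(points, config) {
  anchor <- config$inclusion[[1]]$center
  round(sweep(points, 2, anchor) / config$spacing)
}

#' Generate the inclusion-region lattice
#'
#' Axis-aligned lattice with the configured spacing, anchored at the first
#' inclusion-sphere center; a point is kept iff it lies inside at least one
#' inclusion sphere (closed balls). Point order is deterministic
#' (lexicographic in lattice indices).
#'
#' @param config `grid_config`.
#' @return M x 3 matrix of grid points (Angstrom).
#' @export
generate_inclusion_grid <- function(config) {
  anchor <- config$inclusion[[1]]$center
  s <- config$spacing
  ijk <- NULL
  for (sp in config$inclusion) {
    lo <- ceiling((sp$center - sp$radius - anchor) / s)
    hi <- floor((sp$center + sp$radius - anchor) / s)
    if (any(hi < lo)) next
    g <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
    ijk <- rbind(ijk, g)
  }
  if (is.null(ijk) || nrow(ijk) == 0L)
    return(matrix(numeric(0), 0, 3))
  ijk <- unique(ijk)
  pts <- sweep(ijk * s, 2, anchor, `+`)
  inside <- rep(FALSE, nrow(pts))
  for (sp in config$inclusion) {
    d2 <- rowSums(sweep(pts, 2, sp$center)^2)
    inside <- inside | d2 <= sp$radius^2 + 1e-12
  }
  pts <- pts[inside, , drop = FALSE]
  ijk <- ijk[inside, , drop = FALSE]
  ord <- order(ijk[, 3], ijk[, 2], ijk[, 1])
  pts[ord, , drop = FALSE]
}

.heavy_indices <- function(group) {
  if (inherits(group, "atom_group")) group$indices else as.integer(group)
}

.frame_coords <- function(frame) {
  if (inherits(frame, "md_structure")) frame$coords else as.matrix(frame)
}

#' Prune grid points near receptor atoms
#'
#' In "center" mode a point is dropped when its distance to any heavy-atom
#' center is <= distance_cut; in "vdw" mode when it is <=
#' (vdw radius + distance_cut) of any heavy atom.
#'
#' @param points M x 3 grid points.
#' @param frame `md_structure` (needed for vdw mode) or N x 3 matrix.
#' @param heavy_group `atom_group` of receptor heavy atoms.
#' @param config `grid_config`.
#' @param atoms optional atom table when `frame` is a bare matrix.
#' @return pruned point matrix (subset of `points`).
#' @export
prune_by_receptor_proximity <- function(points, frame, heavy_group, config,
                                        atoms = NULL) {
  if (nrow(points) == 0L) return(points)
  idx <- .heavy_indices(heavy_group)
  coords <- .frame_coords(frame)[idx, , drop = FALSE]
  if (nrow(coords) == 0L) return(points)
  if (config$proximity_mode == "vdw") {
    if (is.null(atoms)) atoms <- .atoms_of(frame)
    el <- atoms$element[idx]
    r <- config$vdw_radii[el]
    r[is.na(r)] <- max(config$vdw_radii)
    thr <- unname(r) + config$distance_cut
  } else {
    thr <- rep(config$distance_cut, nrow(coords))
  }
  keep <- rep(TRUE, nrow(points))
  # chunk the M x N distance computation to bound memory
  chunk <- max(1L, floor(4e6 / nrow(coords)))
  a2 <- rowSums(coords^2)
  thr2 <- thr^2
  uniform <- length(unique(thr2)) == 1L
  tc <- t(coords)
  for (start in seq(1L, nrow(points), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(points))
    p <- points[rows, , drop = FALSE]
    d2 <- outer(rowSums(p^2), a2, `+`) - 2 * p %*% tc
    hit <- if (uniform) d2 <= thr2[1]
           else d2 <= rep(thr2, each = length(rows))
    keep[rows] <- rowSums(hit) == 0L
  }
  points[keep, , drop = FALSE]
}

#' Triangulated 3D convex hull (incremental algorithm)
#'
#' @param pts n x 3 point matrix, n >= 4 and not all coplanar.
#' @param tol degeneracy tolerance in Angstrom.
#' @return list with `faces` (F x 3 vertex indices), unit outward `normals`
#'   (F x 3) and `offsets` (length F): x is inside iff
#'   normals %*% x <= offsets for all faces.
#' @export
convex_hull_3d <- function(pts, tol = 1e-7) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 4L) stop("convex hull needs at least 4 points")
  # initial non-degenerate tetrahedron from extreme points
  i1 <- which.min(pts[, 1])
  d1 <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d1)
  if (sqrt(d1[i2]) < tol) stop("degenerate hull: points coincide")
  u <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(rel[, 2] * u[3] - rel[, 3] * u[2],
              rel[, 3] * u[1] - rel[, 1] * u[3],
              rel[, 1] * u[2] - rel[, 2] * u[1])
  dline <- rowSums(cr^2)
  i3 <- which.max(dline)
  if (sqrt(dline[i3]) / sqrt(sum(u^2)) < tol)
    stop("degenerate hull: points are collinear")
  v <- pts[i3, ] - pts[i1, ]
  nrm <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  dplane <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(dplane)
  if (dplane[i4] < tol) stop("degenerate hull: points are coplanar")

  interior <- colMeans(pts[c(i1, i2, i3, i4), ])
  mk_face <- function(a, b, c) {
    e1 <- pts[b, ] - pts[a, ]; e2 <- pts[c, ] - pts[a, ]
    nf <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    nf <- nf / sqrt(sum(nf^2))
    off <- sum(nf * pts[a, ])
    if (sum(nf * interior) > off) { nf <- -nf; off <- -off }
    list(v = c(a, b, c), n = nf, o = off)
  }
  faces <- list(mk_face(i1, i2, i3), mk_face(i1, i2, i4),
                mk_face(i1, i3, i4), mk_face(i2, i3, i4))

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    N <- do.call(rbind, lapply(faces, `[[`, "n"))
    O <- vapply(faces, `[[`, numeric(1), "o")
    vis <- as.numeric(N %*% pts[p, ]) > O + tol
    if (!any(vis)) next
    vfaces <- faces[vis]
    edges <- do.call(rbind, lapply(vfaces, function(f)
      rbind(f$v[c(1, 2)], f$v[c(2, 3)], f$v[c(3, 1)])))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    faces <- faces[!vis]
    for (e in seq_len(nrow(horizon)))
      faces[[length(faces) + 1L]] <- mk_face(horizon[e, 1], horizon[e, 2], p)
  }
  list(faces = do.call(rbind, lapply(faces, `[[`, "v")),
       normals = do.call(rbind, lapply(faces, `[[`, "n")),
       offsets = vapply(faces, `[[`, numeric(1), "o"))
}

#' Test points against a convex hull
#'
#' @param points M x 3 matrix.
#' @param hull result of [convex_hull_3d()].
#' @param tol boundary tolerance in Angstrom (points within `tol` of a face
#'   plane count as inside).
#' @return logical vector: inside or on the hull.
#' @export
points_in_hull <- function(points, hull, tol = 1e-7) {
  if (nrow(points) == 0L) return(logical(0))
  s <- points %*% t(hull$normals)
  rowSums(s > rep(hull$offsets + tol, each = nrow(points))) == 0L
}

#' Drop grid points outside the receptor convex hull
#'
#' Keeps points strictly inside or on the convex hull of the receptor
#' heavy-atom centers.
#'
#' @param points M x 3 grid points.
#' @param frame `md_structure` or N x 3 matrix.
#' @param heavy_group `atom_group` of receptor heavy atoms.
#' @return pruned point matrix.
#' @export
prune_outside_convex_hull <- function(points, frame, heavy_group) {
  idx <- .heavy_indices(heavy_group)
  coords <- .frame_coords(frame)[idx, , drop = FALSE]
  hull <- convex_hull_3d(coords)
  points[points_in_hull(points, hull), , drop = FALSE]
}

# 26-neighborhood integer key offsets for a lattice encoded as
# key = i + j*B + k*B^2 with B large enough to avoid collisions.
.neighbor_deltas <- function(B) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  g[, 1] + g[, 2] * B + g[, 3] * B * B
}

#' Contiguity filter on lattice points
#'
#' Iteratively deletes points with fewer than `contiguity_criterion`
#' neighbors in their 26-neighborhood until a fixed point is reached, then
#' keeps only connected components (26-connectivity) that contain the
#' lattice point nearest to an inclusion-sphere center (falling back to the
#' nearest surviving point within that sphere when the snapped point itself
#' was pruned).
#'
#' @param points M x 3 grid points on the config lattice.
#' @param config `grid_config`.
#' @return filtered point matrix.
#' @export
contiguity_filter <- function(points, config) {
  if (nrow(points) == 0L) return(points)
  ijk <- .lattice_ijk(points, config)
  B <- 2L * (max(abs(ijk)) + 2L)
  keys <- ijk[, 1] + ijk[, 2] * B + ijk[, 3] * B * B
  deltas <- .neighbor_deltas(B)
  alive <- rep(TRUE, length(keys))

  repeat {
    ak <- keys[alive]
    nb <- outer(ak, deltas, `+`)
    cnt <- rowSums(matrix(nb %in% ak, nrow = length(ak)))
    drop <- cnt < config$contiguity_criterion
    if (!any(drop)) break
    alive[alive] <- !drop
    if (!any(alive)) return(points[alive, , drop = FALSE])
  }

  # connected components over surviving points
  ak <- keys[alive]
  pos <- which(alive)
  nbmat <- matrix(match(outer(ak, deltas, `+`), ak), nrow = length(ak))
  comp <- rep(NA_integer_, length(ak))
  cid <- 0L
  for (i in seq_along(ak)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    comp[i] <- cid
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      nbs <- nbmat[cur, ]
      nbs <- nbs[!is.na(nbs)]
      new <- nbs[is.na(comp[nbs])]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }

  # seed components: snapped inclusion-sphere centers (or nearest survivor
  # within the sphere when the snapped point is gone)
  anchor <- config$inclusion[[1]]$center
  surv_pts <- points[pos, , drop = FALSE]
  seed_comps <- integer(0)
  for (sp in config$inclusion) {
    skey <- {
      sijk <- round((sp$center - anchor) / config$spacing)
      sijk[1] + sijk[2] * B + sijk[3] * B * B
    }
    hit <- match(skey, ak)
    if (is.na(hit)) {
      d2 <- rowSums(sweep(surv_pts, 2, sp$center)^2)
      if (length(d2) && min(d2) <= sp$radius^2) hit <- which.min(d2)
    }
    if (!is.na(hit)) seed_comps <- c(seed_comps, comp[hit])
  }
  keep <- comp %in% seed_comps
  points[pos[keep], , drop = FALSE]
}

#' Pocket volume of one frame
#'
#' Full pipeline: inclusion grid, receptor-proximity pruning, optional
#' convex-hull exclusion, contiguity filtering; the volume is the surviving
#' point count times spacing cubed.
#'
#' @param frame `md_structure` (or N x 3 matrix with `atoms` supplied).
#' @param heavy_group `atom_group` of receptor heavy atoms.
#' @param config `grid_config`.
#' @param frame_index index stored in the result.
#' @param atoms optional atom table when `frame` is a matrix.
#' @return list (class `volume_result`) with frame_index, n_points, volume
#'   (cubic Angstrom).
#' @export
pocket_volume <- function(frame, heavy_group, config, frame_index = 1L,
                          atoms = NULL) {
  pts <- generate_inclusion_grid(config)
  pts <- prune_by_receptor_proximity(pts, frame, heavy_group, config, atoms)
  if (config$convex_hull_exclusion && nrow(pts) > 0L)
    pts <- prune_outside_convex_hull(pts, frame, heavy_group)
  pts <- contiguity_filter(pts, config)
  structure(list(frame_index = frame_index, n_points = nrow(pts),
                 volume = nrow(pts) * config$spacing^3),
            class = "volume_result")
}

#' Per-frame pocket volumes over a trajectory
#'
#' @param trajectory `md_trajectory`.
#' @param heavy_group `atom_group` of receptor heavy atoms.
#' @param config `grid_config`.
#' @param frame_indices frames to analyse (default all).
#' @return data.frame with frame_index, n_points, volume.
#' @export
trajectory_volumes <- function(trajectory, heavy_group, config,
                               frame_indices = NULL) {
  if (is.null(frame_indices)) frame_indices <- seq_along(trajectory$frames)
  res <- lapply(frame_indices, function(f)
    pocket_volume(get_frame(trajectory, f), heavy_group, config, f))
  data.frame(frame_index = vapply(res, `[[`, integer(1), "frame_index"),
             n_points = vapply(res, `[[`, integer(1), "n_points"),
             volume = vapply(res, `[[`, numeric(1), "volume"))
}

# evaluate expr under a temporary seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Randomly subsample frame indices
#'
#' Draws `floor(F * fraction)` distinct frame indices uniformly without
#' replacement, reproducibly under the given seed.
#'
#' @param trajectory `md_trajectory` or an integer frame count.
#' @param fraction fraction of frames in (0, 1].
#' @param seed RNG seed.
#' @return sorted integer vector of frame indices.
#' @export
sample_frames <- function(trajectory, fraction, seed) {
  F <- if (inherits(trajectory, "md_trajectory")) length(trajectory$frames)
       else as.integer(trajectory)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- floor(F * fraction)
  sort(.with_seed(seed, sample.int(F, k)))
}

#' Bin pocket volumes into bands
#'
#' Right-open bins defined by `bin_edges`, with the last bin unbounded.
#' Defaults match the reported low / intermediate / large bands
#' (0-25, 25-70, >= 70 cubic Angstrom).
#'
#' @param volumes numeric vector of volumes.
#' @param bin_edges strictly increasing lower edges.
#' @return list (class `volume_distribution`) with bin_edges, counts,
#'   n_frames.
#' @export
volume_distribution <- function(volumes, bin_edges = c(0, 25, 70)) {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  if (any(volumes < bin_edges[1])) stop("volumes below the first bin edge")
  bin <- findInterval(volumes, bin_edges)
  counts <- tabulate(bin, nbins = length(bin_edges))
  structure(list(bin_edges = bin_edges, counts = counts,
                 n_frames = length(volumes)),
            class = "volume_distribution")
}

.large_fraction <- function(x, threshold) {
  if (inherits(x, "volume_distribution")) {
    i <- findInterval(threshold, x$bin_edges)
    if (!isTRUE(all.equal(threshold, x$bin_edges[i])))
      stop("threshold must coincide with a bin edge when a distribution is given")
    sum(x$counts[i:length(x$counts)]) / x$n_frames
  } else {
    mean(x >= threshold)
  }
}

#' Fold enrichment of large pocket volumes
#'
#' Ratio of the fraction of frames with volume >= threshold in the
#' alternative condition over the reference condition.
#'
#' @param alt,ref numeric volume vectors or `volume_distribution`s.
#' @param threshold large-volume threshold in cubic Angstrom (default 70).
#' @return list with fold, frac_alt, frac_ref. A reference fraction of zero
#'   yields an infinite fold with a warning.
#' @export
large_volume_fold <- function(alt, ref, threshold = 70) {
  fa <- .large_fraction(alt, threshold)
  fr <- .large_fraction(ref, threshold)
  if (fr == 0) {
    if (fa > 0) warning("reference large-volume fraction is 0; fold is infinite")
    fold <- if (fa > 0) Inf else NaN
  } else {
    fold <- fa / fr
  }
  list(fold = fold, frac_alt = fa, frac_ref = fr)
}

#' Triplicate subsampled large-volume comparison
#'
#' Draws three seeded 10% frame subsamples per condition, computes the
#' large-volume fraction of each, and reports the per-subsample folds plus
#' the equal-variance t-test over the triplicate fractions.
#'
#' @param alt_volumes,ref_volumes per-frame volume vectors.
#' @param threshold large-volume threshold (default 70).
#' @param fraction subsample fraction (default 0.1).
#' @param seed base RNG seed; replicate r uses seed + r.
#' @param n_replicates number of subsamples (default 3).
#' @return list with per-replicate folds, fractions, the pooled fold, and
#'   the `ttest_result` over the fractions.
#' @export
triplicate_volume_folds <- function(alt_volumes, ref_volumes, threshold = 70,
                                    fraction = 0.1, seed = 1,
                                    n_replicates = 3) {
  frac_alt <- frac_ref <- folds <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    ia <- sample_frames(length(alt_volumes), fraction, seed + r)
    ir <- sample_frames(length(ref_volumes), fraction, seed + 1000L + r)
    lv <- large_volume_fold(alt_volumes[ia], ref_volumes[ir], threshold)
    folds[r] <- lv$fold
    frac_alt[r] <- lv$frac_alt
    frac_ref[r] <- lv$frac_ref
  }
  pooled <- large_volume_fold(alt_volumes, ref_volumes, threshold)
  ttest <- if (n_replicates >= 2)
    ttest_equal_var_two_tailed(frac_alt, frac_ref) else NULL
  list(folds = folds, frac_alt = frac_alt, frac_ref = frac_ref,
       pooled_fold = pooled$fold, ttest = ttest)
}
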