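sphere_cfg <- function(spacing, r = 3, mode = "center", hull = FALSE,
                       centers = list(c(0, 0, 0)), contiguity = 3) {
  grid_config(spacing = spacing, distance_cut = 0.4,
              contiguity_criterion = contiguity, convex_hull_exclusion = hull,
              proximity_mode = mode,
              inclusion = lapply(centers, inclusion_sphere, radius = r))
}

test_that("inclusion grid volume approximates the analytic ball and scales with spacing", {
  v_ball <- 4 / 3 * pi * 27
  m04 <- nrow(generate_inclusion_grid(sphere_cfg(0.4)))
  expect_lt(abs(m04 * 0.4^3 - v_ball) / v_ball, 0.05)

  m02 <- nrow(generate_inclusion_grid(sphere_cfg(0.2)))
  expect_equal(m02 / m04, 8, tolerance = 0.05)

  # two disjoint spheres: counts add
  two <- sphere_cfg(0.4, centers = list(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(nrow(generate_inclusion_grid(two)), 2 * m04,
               tolerance = 0.01)
})

test_that("proximity pruning matches the brute-force oracle in both modes", {
  cfg <- sphere_cfg(0.5)
  pts <- generate_inclusion_grid(cfg)

  # no receptor in range: unchanged
  far <- md_structure(make_atoms("CA", "C"), matrix(c(50, 0, 0), 1, 3))
  expect_equal(prune_by_receptor_proximity(pts, far, 1L, cfg), pts)

  # single atom at the sphere center, center mode
  one <- md_structure(make_atoms("CA", "C"), matrix(0, 1, 3))
  got <- prune_by_receptor_proximity(pts, one, 1L, cfg)
  want <- oracle_prune(pts, matrix(0, 1, 3), 0.4)
  expect_equal(got, want)

  # several atoms, vdw mode, mixed elements
  set.seed(8)
  xyz <- matrix(runif(15, -2, 2), 5, 3)
  atoms <- make_atoms(paste0("A", 1:5), c("C", "N", "O", "S", "C"))
  st <- md_structure(atoms, xyz)
  vcfg <- sphere_cfg(0.5, mode = "vdw")
  got2 <- prune_by_receptor_proximity(pts, st, 1:5, vcfg)
  thr <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)[atoms$element] + 0.4
  expect_equal(got2, oracle_prune(pts, xyz, thr))

  # saturation: dense receptor filling the sphere removes everything
  dense <- as.matrix(expand.grid(x = seq(-3, 3, 1), y = seq(-3, 3, 1),
                                 z = seq(-3, 3, 1)))
  dst <- md_structure(make_atoms(rep("CA", nrow(dense)), "C"), dense)
  expect_equal(nrow(prune_by_receptor_proximity(pts, dst, seq_len(nrow(dense)),
                                                vcfg)), 0L)
})

test_that("convex hull membership matches the half-space oracle on the unit cube", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  hull <- convex_hull_3d(cube)
  set.seed(9)
  pts <- matrix(runif(3000, -0.5, 1.5), 1000, 3)
  inside <- points_in_hull(pts, hull)
  oracle <- apply(pts, 1, function(p) all(p >= 0 & p <= 1))
  expect_equal(inside, unname(oracle))

  # tetrahedron: interior point kept, exterior dropped
  tet <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4))
  st <- md_structure(make_atoms(rep("CA", 4), "C"), tet)
  inpts <- rbind(c(0.5, 0.5, 0.5), c(1, 1, 1))
  expect_equal(prune_outside_convex_hull(inpts, st, 1:4), inpts)
  outpts <- rbind(c(5, 5, 5), c(-1, 0, 0))
  expect_equal(nrow(prune_outside_convex_hull(outpts, st, 1:4)), 0L)

  flat <- md_structure(make_atoms(rep("CA", 4), "C"),
                       cbind(runif(4), runif(4), 0))
  expect_error(prune_outside_convex_hull(inpts, flat, 1:4), "degenerate")
})

test_that("contiguity filtering matches iterative deletion plus seeded flood fill", {
  cfg <- sphere_cfg(1, r = 3, contiguity = 3)
  # full 5x5x5 block around the seed: unchanged
  block <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  dimnames(block) <- NULL
  got <- contiguity_filter(block, cfg)
  expect_equal(nrow(got), 125L)

  # a single isolated point is removed
  iso <- rbind(block, c(10, 10, 10))
  expect_equal(nrow(contiguity_filter(iso, cfg)), 125L)

  # two components; only the seeded one survives
  far_block <- sweep(block, 2, c(30, 0, 0), `+`)
  both <- rbind(block, far_block)
  kept <- contiguity_filter(both, cfg)
  expect_equal(nrow(kept), 125L)
  expect_true(all(kept[, 1] <= 2))

  # randomized equivalence against the brute-force oracle
  set.seed(10)
  for (rep in 1:5) {
    ijk <- unique(matrix(sample(-3:3, 240, TRUE), ncol = 3))
    pts <- ijk * 1.0
    alive <- oracle_contiguity_prune(ijk, 3)
    surv <- ijk[alive, , drop = FALSE]
    expected <- if (nrow(surv)) {
      comp <- oracle_components(surv)
      seedrow <- which(surv[, 1] == 0 & surv[, 2] == 0 & surv[, 3] == 0)
      if (length(seedrow)) {
        surv[comp == comp[seedrow], , drop = FALSE]
      } else {
        # fallback: nearest survivor to the origin within the sphere
        d2 <- rowSums(surv^2)
        if (min(d2) <= 9) {
          comp_id <- comp[which.min(d2)]
          surv[comp == comp_id, , drop = FALSE]
        } else surv[0, , drop = FALSE]
      }
    } else surv
    got <- contiguity_filter(pts, cfg)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                 expected[order(expected[, 1], expected[, 2], expected[, 3]),
                          , drop = FALSE] * 1.0)
  }
})

test_that("the full volume pipeline attains its analytic bounds", {
  cfg <- sphere_cfg(0.4)
  grid_vol <- nrow(generate_inclusion_grid(cfg)) * 0.4^3

  # receptor-free frame: the whole inclusion grid survives
  far <- md_structure(make_atoms("CA", "C"), matrix(c(99, 0, 0), 1, 3))
  pv <- pocket_volume(far, 1L, cfg)
  expect_equal(pv$volume, grid_vol)
  expect_equal(pv$volume, pv$n_points * 0.4^3)

  # hollow shell recovers the inflated-cavity volume within 10%
  shell <- make_pocket_shell(3.0)
  hv <- select_atoms(shell$structure, "heavy")
  got <- pocket_volume(shell$structure, hv, cfg)
  expect_lt(abs(got$volume - shell$analytic_volume) / shell$analytic_volume,
            0.10)

  # volume never increases as receptor atoms accumulate
  set.seed(11)
  xyz <- matrix(runif(36, -2.5, 2.5), 12, 3)
  atoms <- make_atoms(paste0("A", 1:12), "C")
  prev <- Inf
  for (n in c(2, 5, 8, 12)) {
    st <- md_structure(atoms[1:n, ], xyz[1:n, , drop = FALSE])
    v <- pocket_volume(st, seq_len(n), cfg)$volume
    expect_lte(v, prev)
    prev <- v
  }
})

test_that("frame subsampling is seeded, distinct and correctly sized", {
  idx <- sample_frames(5000, 0.1, seed = 3)
  expect_equal(length(idx), 500L)
  expect_equal(length(unique(idx)), 500L)
  expect_true(all(idx >= 1 & idx <= 5000))
  expect_equal(sample_frames(5000, 0.1, seed = 3), idx)
  expect_false(identical(sample_frames(5000, 0.1, seed = 4), idx))
  expect_equal(sample_frames(30, 1, seed = 1), 1:30)
  expect_error(sample_frames(10, 0, seed = 1), "fraction")
})

test_that("volume binning uses right-open bands and conserves frames", {
  d <- volume_distribution(c(10, 30, 80), c(0, 25, 70))
  expect_equal(d$counts, c(1, 1, 1))
  expect_equal(sum(d$counts), d$n_frames)
  expect_equal(volume_distribution(rep(0, 5))$counts, c(5, 0, 0))
  # edge values fall in the upper band
  expect_equal(volume_distribution(c(25, 70))$counts, c(0, 1, 1))

  set.seed(12)
  v <- runif(1000, 0, 100)
  d2 <- volume_distribution(v, c(0, 25, 70))
  expect_equal(d2$counts,
               c(sum(v < 25), sum(v >= 25 & v < 70), sum(v >= 70)))
  expect_error(volume_distribution(v, c(0, 0, 70)), "strictly increasing")
})

test_that("large-volume fold has ratio semantics with a guarded zero reference", {
  v <- c(rep(10, 50), rep(80, 50))
  expect_equal(large_volume_fold(v, v)$fold, 1)

  alt <- c(rep(90, 17), rep(10, 983))
  ref <- c(rep(90, 2), rep(10, 998))
  expect_equal(large_volume_fold(alt, ref)$fold, 8.5)

  expect_warning(inf <- large_volume_fold(alt, rep(10, 100)), "infinite")
  expect_equal(inf$fold, Inf)

  tri <- triplicate_volume_folds(alt, ref, seed = 5)
  expect_length(tri$folds, 3)
  tri2 <- triplicate_volume_folds(alt, ref, seed = 5)
  expect_identical(tri$folds, tri2$folds)
  expect_s3_class(tri$ttest, "ttest_result")
})

test_that("grid volume error strictly decreases with spacing refinement", {
  v_ball <- 4 / 3 * pi * 27
  errs <- vapply(c(0.8, 0.4, 0.2), function(s)
    abs(nrow(generate_inclusion_grid(sphere_cfg(s))) * s^3 - v_ball),
    numeric(1))
  expect_true(all(diff(errs) < 0))
})
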