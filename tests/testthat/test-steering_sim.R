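test_that("steering energy is the zero-rest-length harmonic of the centroid distance", {
  sys <- tiny_system(bead_pos = list(c(10, 0, 0)))
  f <- steering_force(0.2, atom_group(2L), atom_group(1L))
  expect_equal(steering_energy(sys$coords, f, sys$atoms), 10.0)

  at0 <- sys$coords; at0[2, ] <- 0.0001 * at0[2, ]
  expect_equal(steering_energy(at0, f, sys$atoms), 0, tolerance = 1e-6)
  f0 <- steering_force(0, atom_group(2L), atom_group(1L))
  expect_equal(steering_energy(sys$coords, f0, sys$atoms), 0)
  expect_error(steering_force(-1, atom_group(1L), atom_group(2L)), ">= 0")
})

test_that("steering energy depends only on the centroid distance", {
  sys <- tiny_system(bead_pos = list(c(10, 0, 0)))
  f <- steering_force(0.2, atom_group(2L), atom_group(1L))
  e0 <- steering_energy(sys$coords, f, sys$atoms)
  set.seed(15)
  for (i in 1:5)
    expect_equal(steering_energy(oracle_rigid(sys$coords), f, sys$atoms), e0,
                 tolerance = 1e-9)
})

test_that("total forces combine steering, bonds and repulsion as documented", {
  sys <- tiny_system(bead_pos = list(c(10, 0, 0)))
  f <- list(steering_force(0.2, atom_group(2L), atom_group(1L)))
  F <- total_forces(sys$coords, sys, f)
  expect_equal(F[1, ], c(0, 0, 0))             # receptor immobile
  expect_equal(F[2, ], c(-2, 0, 0))            # k*d = 0.2*10 toward target

  # no forces anywhere: zero
  expect_equal(total_forces(sys$coords, sys, list()),
               matrix(0, 2, 3))

  # isolated bonded two-bead ligand obeys Newton's third law
  sys2 <- tiny_system(2, list(c(10, 0, 0), c(13, 0, 0)), bond = TRUE)
  F2 <- total_forces(sys2$coords, sys2, list())
  expect_equal(colSums(F2), c(0, 0, 0))
  stretched <- sys2$coords; stretched[3, 1] <- 14
  F3 <- total_forces(stretched, sys2, list())
  expect_equal(colSums(F3), c(0, 0, 0), tolerance = 1e-12)
  expect_gt(F3[2, 1], 0)   # pulled toward the displaced partner

  # repulsion is purely repulsive and errors on exact overlap
  sys3 <- tiny_system(bead_pos = list(c(1.5, 0, 0)))
  F4 <- total_forces(sys3$coords, sys3, list())
  expect_equal(F4[2, 1], 6 * (2 - 1.5), tolerance = 1e-12)
  outside <- sys3$coords; outside[2, 1] <- 2.5
  expect_equal(total_forces(outside, sys3, list())[2, ], c(0, 0, 0))
  zero <- sys3$coords; zero[2, ] <- 0
  expect_error(total_forces(zero, sys3, list()), "direction undefined")
})

test_that("the overdamped step has the exact deterministic limit and is seeded", {
  sys <- tiny_system(bead_pos = list(c(10, 0, 0)), mass = 100)
  f <- list(steering_force(0.2, atom_group(2L), atom_group(1L)))
  p <- sim_params(dt_ps = 0.01, temperature_K = 0, seed = 1)
  nxt <- step_overdamped(sys$coords, sys, f, p)
  # mobility = 100/(m*gamma) with the kJ/mol -> Da A^2/ps^2 factor 100
  expect_equal(nxt[2, 1] - 10, (100 / (100 * 1)) * (-2) * 0.01,
               tolerance = 1e-12)
  expect_equal(nxt[1, ], c(0, 0, 0))

  # zero forces at T = 0: frame unchanged
  expect_equal(step_overdamped(sys$coords, sys, list(), p), sys$coords)

  # fixed seed: bit-identical successor frames
  p300 <- sim_params(dt_ps = 0.01, temperature_K = 300)
  set.seed(99); a <- step_overdamped(sys$coords, sys, f, p300)
  set.seed(99); b <- step_overdamped(sys$coords, sys, f, p300)
  expect_identical(a, b)

  pbig <- sim_params(dt_ps = 10, temperature_K = 0)
  expect_error(step_overdamped(sys$coords, sys, f, pbig), "reduce dt")
})

test_that("replicates record the expected frames and are reproducible", {
  sys <- tiny_system(bead_pos = list(c(10, 0, 0)))
  f <- list(steering_force(0.2, atom_group(2L), atom_group(1L)))
  p <- sim_params(dt_ps = 0.01, n_steps = 1000, record_stride = 100, seed = 5)
  tr <- run_replicate(sys, f, p)
  expect_equal(length(tr$frames), 11L)
  expect_equal(tr$frame_interval_ps, 1)
  tr2 <- run_replicate(sys, f, p)
  expect_identical(tr$frames, tr2$frames)

  # T = 0 steering-only descent: centroid distance non-increasing
  p0 <- sim_params(dt_ps = 0.01, n_steps = 500, record_stride = 10,
                   temperature_K = 0, seed = 1)
  tr0 <- run_replicate(sys, f, p0)
  d <- vapply(tr0$frames, function(fr) sqrt(sum((fr[2, ] - fr[1, ])^2)),
              numeric(1))
  expect_true(all(diff(d) <= 1e-12))
  expect_lt(d[length(d)], d[1])
})

test_that("the fast replicate path reproduces the reference integrator", {
  sys <- make_toy_association_system("open")
  p <- sim_params(n_steps = 150, record_stride = 50, seed = 21)
  fast <- run_replicate(sys, sys$forces, p)
  slow <- local({
    coords <- sys$coords
    frames <- list(coords)
    steermd:::.with_seed(21, {
      for (s in 1:150) {
        coords <- step_overdamped(coords, sys, sys$forces, p)
        if (s %% 50 == 0) frames[[length(frames) + 1]] <- coords
      }
    })
    frames
  })
  for (i in seq_along(slow))
    expect_equal(fast$frames[[i]], slow[[i]], tolerance = 1e-12)
})

test_that("ensembles use base_seed + replicate and independent noise", {
  sys <- tiny_system(bead_pos = list(c(10, 0, 0)))
  f <- list(steering_force(0.2, atom_group(2L), atom_group(1L)))
  p <- sim_params(dt_ps = 0.01, n_steps = 200, record_stride = 50)
  ens <- run_ensemble(sys, f, p, n_replicates = 3, base_seed = 40)
  expect_length(ens, 3)
  expect_false(identical(ens[[1]]$frames, ens[[2]]$frames))
  expect_false(identical(ens[[2]]$frames, ens[[3]]$frames))

  ens2 <- run_ensemble(sys, f, p, n_replicates = 3, base_seed = 40)
  for (i in 1:3) expect_identical(ens[[i]]$frames, ens2[[i]]$frames)

  # replicate i is exactly the run with seed base_seed + i
  p1 <- p; p1$seed <- 41L
  expect_identical(run_replicate(sys, f, p1)$frames, ens[[1]]$frames)
  expect_error(run_ensemble(sys, f, p, 0, 1), "n_replicates")
})
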