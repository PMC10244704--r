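test_that("fixed-column PDB records parse to the documented fields", {
  rec <- paste0("ATOM      1  NZ  LYS A  36       1.000   2.000   3.000",
                "  1.00  0.00           N")
  tf <- withr::local_tempfile(lines = rec)
  tr <- read_pdb(tf)
  expect_equal(length(tr$frames), 1L)
  a <- tr$atoms
  expect_equal(a$name, "NZ")
  expect_equal(a$element, "N")
  expect_equal(a$resname, "LYS")
  expect_equal(a$resid, 36L)
  expect_equal(a$chain, "A")
  expect_true(a$is_heavy)
  expect_equal(tr$frames[[1]][1, ], c(1, 2, 3))
})

test_that("multi-MODEL files give one frame per MODEL with shared topology", {
  atoms <- make_atoms(c("N", "CA", "C"), c("N", "C", "C"), resid = 1L,
                      resname = "GLY")
  fr <- list(matrix(rnorm(9), 3, 3), matrix(rnorm(9), 3, 3))
  tf <- withr::local_tempfile()
  write_pdb(md_trajectory(atoms, fr), tf)
  tr <- read_pdb(tf)
  expect_equal(length(tr$frames), 2L)
  expect_equal(nrow(tr$atoms), 3L)
})

test_that("PDB round trip preserves coordinates at format precision", {
  atoms <- make_atoms(c("NZ", "CD", "CE", "SD"), c("N", "C", "C", "S"),
                      resid = c(36L, 36L, 200L, 200L),
                      resname = c("LYS", "LYS", "SAM", "SAM"))
  fr <- lapply(1:3, function(i) matrix(runif(12, -50, 50), 4, 3))
  tf <- withr::local_tempfile()
  orig <- md_trajectory(atoms, fr)
  write_pdb(orig, tf)
  back <- read_pdb(tf)
  for (f in 1:3)
    expect_equal(back$frames[[f]], round(orig$frames[[f]], 3))
  expect_equal(back$atoms$name, orig$atoms$name)
  expect_equal(back$atoms$element, orig$atoms$element)
})

test_that("PDB reader enforces its error and altloc contracts", {
  base <- c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL")
  tf <- withr::local_tempfile(lines = base)
  expect_error(read_pdb(tf), "MODEL")

  bad <- "ATOM      1  CA  GLY A   1       x.000   0.000   0.000  1.00  0.00           C"
  tf2 <- withr::local_tempfile(lines = bad)
  expect_error(read_pdb(tf2), "line 1")

  alt <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA BGLY A   1       0.500   0.000   0.000  1.00  0.00           C")
  tf3 <- withr::local_tempfile(lines = alt)
  expect_warning(tr <- read_pdb(tf3), "altloc")
  expect_equal(nrow(tr$atoms), 1L)
})

test_that("element inference falls back to the atom-name convention", {
  recs <- c(
    "ATOM      1  NE1 TRP A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2 1HB  ALA A   2       0.000   0.000   0.000  1.00  0.00")
  tf <- withr::local_tempfile(lines = recs)
  tr <- read_pdb(tf)
  expect_equal(tr$atoms$element, c("N", "H"))
  expect_equal(tr$atoms$is_heavy, c(TRUE, FALSE))
})

test_that("PDB writer formats origin coordinates and rejects overflow", {
  s <- md_structure(make_atoms("CA", "C"), matrix(0, 1, 3))
  tf <- withr::local_tempfile()
  write_pdb(s, tf)
  txt <- readLines(tf)
  expect_equal(sum(startsWith(txt, "MODEL")), 1L)
  expect_true(any(grepl("   0.000   0.000   0.000", txt, fixed = TRUE)))
  expect_equal(txt[length(txt)], "END")

  big <- md_structure(make_atoms("CA", "C"), matrix(c(1e5, 0, 0), 1, 3))
  expect_error(write_pdb(big, tf), "overflow")
  expect_error(md_trajectory(make_atoms("CA", "C"), list()), "at least one")
})

test_that("XYZ round trip is stable and the count line is enforced", {
  atoms <- make_atoms(c("C", "N", "S", "H"), c("C", "N", "S", "H"))
  fr <- list(matrix(runif(12, -9, 9), 4, 3), matrix(runif(12, -9, 9), 4, 3))
  tf <- withr::local_tempfile()
  write_xyz(md_trajectory(atoms, fr), tf)
  back <- read_xyz(tf)
  expect_equal(length(back$frames), 2L)
  expect_equal(back$atoms$element, atoms$element)
  for (f in 1:2) expect_equal(back$frames[[f]], fr[[f]], tolerance = 1e-6)

  tf2 <- withr::local_tempfile(lines = c("3", "short frame", "C 1.5 0 0"))
  expect_error(read_xyz(tf2), "ends early")
  tf3 <- withr::local_tempfile(lines = c("1", "ok", "C 1.5 0 0"))
  one <- read_xyz(tf3)
  expect_equal(one$frames[[1]][1, ], c(1.5, 0, 0))
  expect_equal(one$atoms$element, "C")
})

test_that("the selector mini-language matches topology-only and in order", {
  atoms <- make_atoms(
    name = c("C", "H1", "H2", "H3", "H4", "NZ", "N", "CA", "C"),
    element = c("C", "H", "H", "H", "H", "N", "N", "C", "C"),
    resid = c(rep(5L, 5), 36L, 1202L, 1202L, 1202L),
    resname = c(rep("MET", 5), "LYS", "LEU", "LEU", "LEU"))
  s <- md_structure(atoms, matrix(rnorm(27), 9, 3))

  expect_equal(select_atoms(s, "heavy")$indices, c(1L, 6L, 7L, 8L, 9L))
  expect_equal(select_atoms(s, "resid 5 and heavy")$indices, 1L)
  expect_equal(select_atoms(s, "resid 36 and name NZ")$indices, 6L)
  expect_equal(select_atoms(s, "resid 1202 and name N,CA,C")$indices,
               c(7L, 8L, 9L))
  expect_error(select_atoms(s, "resid 99"), "resid 99")

  # selection is invariant to coordinates
  s2 <- md_structure(atoms, matrix(rnorm(27, 100), 9, 3))
  expect_equal(select_atoms(s2, "heavy")$indices,
               select_atoms(s, "heavy")$indices)
})

test_that("atom groups validate their invariants", {
  expect_error(atom_group(integer(0), "empty"), "empty")
  expect_error(atom_group(c(3, 1)), "strictly increasing")
  expect_error(atom_group(c(1, 5), n_atoms = 4), "exceed")
})

test_that("center of mass honors weighting and is rigidly equivariant", {
  atoms <- make_atoms(c("O", "H1", "H2"), c("O", "H", "H"))
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0))
  expect_equal(center_of_mass(xyz, 1:3, atoms), c(0, 0, 0))
  expect_equal(center_of_mass(xyz, 2L, atoms), c(1, 0, 0))

  two <- make_atoms(c("C1", "C2"), c("C", "C"))
  xy2 <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(center_of_mass(xy2, 1:2, two), c(1, 0, 0))
  expect_equal(center_of_mass(xy2, 1:2, two, weighting = "geometric"),
               c(1, 0, 0))

  # mass weighting shifts toward the heavy atom
  co <- make_atoms(c("C", "O"), c("C", "O"))
  mw <- center_of_mass(xy2, 1:2, co)
  expect_gt(mw[1], 1)

  set.seed(42)
  for (i in 1:10) {
    xyz <- matrix(rnorm(15), 5, 3)
    atoms5 <- make_atoms(paste0("A", 1:5), sample(c("C", "N", "O"), 5, TRUE))
    q <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    tv <- runif(3)
    lhs <- center_of_mass(sweep(xyz %*% t(R), 2, tv, `+`), 1:5, atoms5)
    rhs <- as.numeric(R %*% center_of_mass(xyz, 1:5, atoms5)) + tv
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("unknown elements fall back to the default mass with a warning", {
  expect_warning(m <- element_mass(c("C", "Xx")), "unknown element")
  expect_equal(m, c(12.011, 12.0))
})

test_that("PDB parsing agrees with bio3d on a multi-model fixture", {
  skip_if_not_installed("bio3d")
  atoms <- make_atoms(c("N", "CA", "C", "O"), c("N", "C", "C", "O"),
                      resid = 7L, resname = "ALA")
  fr <- list(matrix(round(runif(12, -20, 20), 3), 4, 3),
             matrix(round(runif(12, -20, 20), 3), 4, 3))
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(md_trajectory(atoms, fr), tf)
  ours <- read_pdb(tf)
  ref <- bio3d::read.pdb(tf, multi = TRUE)
  expect_equal(matrix(ref$xyz[1, ], ncol = 3, byrow = TRUE), ours$frames[[1]])
  expect_equal(matrix(ref$xyz[2, ], ncol = 3, byrow = TRUE), ours$frames[[2]])
  expect_equal(ref$atom$elety, ours$atoms$name)
})
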