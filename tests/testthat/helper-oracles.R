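# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# direct three-inequality membership test for a TS-like geometry
oracle_ts_pass <- function(d, attack, linearity, d_max = 4,
                           attack_c = 109, attack_tol = 30,
                           lin_c = 180, lin_tol = 30) {
  (d < d_max) && (abs(attack - attack_c) <= attack_tol) &&
    (abs(linearity - lin_c) <= lin_tol)
}

# textbook pooled two-sample t-test; CDF via the regularized incomplete
# beta function rather than pt()
oracle_ttest <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- pbeta(df / (df + t^2), df / 2, 1 / 2)
  list(t = t, df = df, p = p)
}

# exhaustive binomial upper tail
oracle_binom_upper <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j),
             numeric(1)))
}

# all-pairs minimum distance
oracle_min_pair_dist <- function(coords, ia, ib) {
  best <- Inf
  for (i in ia) for (j in ib)
    best <- min(best, sqrt(sum((coords[i, ] - coords[j, ])^2)))
  best
}

# brute-force proximity pruning
oracle_prune <- function(points, atoms_xyz, thresholds) {
  keep <- logical(nrow(points))
  for (p in seq_len(nrow(points))) {
    ok <- TRUE
    for (a in seq_len(nrow(atoms_xyz))) {
      if (sqrt(sum((points[p, ] - atoms_xyz[a, ])^2)) <= thresholds[a]) {
        ok <- FALSE
        break
      }
    }
    keep[p] <- ok
  }
  points[keep, , drop = FALSE]
}

# independent flood fill over lattice points (26-connectivity), string keys
oracle_components <- function(ijk) {
  key <- apply(ijk, 1, paste, collapse = ",")
  idx <- seq_len(nrow(ijk))
  lookup <- new.env()
  for (i in idx) assign(key[i], i, envir = lookup)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  comp <- rep(NA_integer_, nrow(ijk))
  cid <- 0
  for (s in idx) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    stack <- s
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(comp[cur])) next
      comp[cur] <- cid
      for (o in seq_len(nrow(offs))) {
        nk <- paste(ijk[cur, ] + offs[o, ], collapse = ",")
        nb <- mget(nk, envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(nb) && is.na(comp[nb])) stack <- c(stack, nb)
      }
    }
  }
  comp
}

# iterative low-neighbor deletion, brute force O(n^2)
oracle_contiguity_prune <- function(ijk, min_neighbors) {
  alive <- rep(TRUE, nrow(ijk))
  repeat {
    ids <- which(alive)
    # neighbors are points at Chebyshev distance exactly 1
    nbr <- vapply(ids, function(i) {
      ch <- apply(abs(sweep(ijk[ids, , drop = FALSE], 2, ijk[i, ])), 1, max)
      sum(ch == 1)
    }, numeric(1))
    drop <- nbr < min_neighbors
    if (!any(drop)) return(alive)
    alive[ids[drop]] <- FALSE
    if (!any(alive)) return(alive)
  }
}

# random rigid transform of an N x 3 coordinate matrix
oracle_rigid <- function(xyz) {
  q <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(xyz %*% t(R), 2, runif(3, -30, 30), `+`)
}

# a tiny two-bead system for simulator unit tests: one steric receptor atom
# at the origin, one or two ligand beads, optional bond
tiny_system <- function(n_beads = 1, bead_pos = list(c(10, 0, 0)),
                        bond = FALSE, mass = 100, k_rep = 6) {
  rec <- md_structure(make_atoms("NZ", "N", resid = 1L, resname = "LYS"),
                      matrix(0, 1, 3))
  lig_atoms <- make_atoms(paste0("B", seq_len(n_beads)),
                          rep("C", n_beads), resid = 500L, resname = "LIG")
  lig_atoms$mass <- rep(mass, n_beads)
  lig <- md_structure(lig_atoms, do.call(rbind, bead_pos))
  bonds <- if (bond && n_beads == 2) {
    r0 <- sqrt(sum((bead_pos[[2]] - bead_pos[[1]])^2))
    data.frame(i = 2L, j = 3L, r0 = r0, k = 10)
  } else data.frame(i = integer(0), j = integer(0), r0 = numeric(0),
                    k = numeric(0))
  toy_system(rec, receptor_radii = 1.0, ligand = lig,
             ligand_radii = rep(1.0, n_beads), bonds = bonds,
             centroid_groups = list(), ts_map = ts_atom_map(1, 2, 3, 4),
             k_rep = k_rep)
}
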