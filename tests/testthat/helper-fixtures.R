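# Shared helpers: random rigid-body transforms, atom permutations, and a
# canonical view of a topology for permutation-invariance checks.

# random proper rotation matrix (QR of a Gaussian matrix, det forced to +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# apply a random rotation + translation to a geometry
rigid_transform <- function(geom, rot = random_rotation(),
                            shift = rnorm(3L, sd = 5)) {
  molecular_geometry(geom$elements,
                     geom$coords %*% t(rot) +
                       matrix(shift, n_atoms(geom), 3L, byrow = TRUE),
                     label = geom$label)
}

# permute atom order; returns the permuted geometry and the permutation
# (new index i holds old atom perm[i])
permute_geometry <- function(geom, perm = sample(n_atoms(geom))) {
  list(geometry = molecular_geometry(geom$elements[perm],
                                     geom$coords[perm, , drop = FALSE],
                                     label = geom$label),
       perm = perm)
}

# topology content in original atom labels, order-independent: set of Rh
# indices, sorted ligand partition, donor pairs, carbene atoms
canonical_topology <- function(topo, to_original = identity) {
  lig <- lapply(topo$ligands, function(a) sort(to_original(a)))
  lig <- lig[order(vapply(lig, min, numeric(1L)))]
  don <- lapply(topo$donors, function(d) {
    m <- cbind(to_original(d$atom), to_original(d$rh))
    m[order(m[, 1L]), , drop = FALSE]
  })
  don <- don[order(vapply(don, function(m) min(m[, 1L]), numeric(1L)))]
  list(rh = sort(to_original(unname(topo$rh_indices))),
       ligands = lig, donors = don,
       carbene = if (is.null(topo$carbene)) NULL
                 else sort(to_original(topo$carbene$atoms)))
}

# textbook two-pass Pearson correlation, independent of stats::cor
textbook_correlation <- function(m) {
  n <- nrow(m); p <- ncol(m)
  mu <- colMeans(m)
  r <- matrix(1, p, p, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    xi <- m[, i] - mu[i]; xj <- m[, j] - mu[j]
    r[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  r
}

# minimum pairwise distance within a set of score-space points
min_pairwise <- function(x) {
  if (nrow(x) < 2L) return(Inf)
  min(dist(x))
}

# a small standard catalyst bundle for descriptor-record tests
test_catalyst <- function(id = "tcat", seed = 11L, ...) {
  make_fixture_catalyst(id, rh_rh_1 = 2.45, rh_rh_2 = 2.47, tilt_1 = 2,
                        tilt_2 = 3, bite_angle = 125, carbene_angle = 118,
                        seed = seed, ...)
}
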