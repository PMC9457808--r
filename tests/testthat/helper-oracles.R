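# Independent oracles and small structural helpers shared across tests.
# These stay deliberately naive (matrix powers, explicit loops, explicit
# pseudo-inverse) so they are independent of the package's own code paths.

# All-pairs shortest paths by Floyd-Warshall on an adjacency matrix.
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Brute-force lag autocorrelation of the influence matrix: explicit
# pseudo-inverse, explicit pair loop.
h4m_brute <- function(xyz, topo, masses, lag = 4) {
  m <- sweep(xyz, 2, colMeans(xyz))
  s <- svd(t(m) %*% m)
  keep <- s$d > 1e-10 * max(s$d)
  pinv <- s$v[, keep, drop = FALSE] %*% diag(1 / s$d[keep], sum(keep)) %*%
    t(s$u[, keep, drop = FALSE])
  H <- m %*% pinv %*% t(m)
  w <- masses / 12.011
  total <- 0
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (is.finite(topo[i, j]) && topo[i, j] == lag && H[i, j] > 0)
      total <- total + H[i, j] * w[i] * w[j]
  total
}

# Reorder the atoms of a molecule by a permutation; descriptors must not
# change.  perm[k] gives the new position of old atom k.
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  atoms <- mol$atoms[inv, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  bonds$i <- perm[bonds$i]; bonds$j <- perm[bonds$j]
  out <- molecule(mol$id, atoms, bonds,
                  coords = if (is.null(mol$coords)) NULL else mol$coords[inv, , drop = FALSE],
                  rings = lapply(mol$rings, function(r) perm[r]))
  out$smiles <- mol$smiles
  out
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

with_coords <- function(mol, xyz) {
  mol$coords <- as.matrix(xyz)
  mol
}
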