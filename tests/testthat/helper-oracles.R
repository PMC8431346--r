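# Independent oracles and small generators used across the test files.
# These deliberately avoid the package's own code paths.

# Long axis of a point set via SVD of the centered coordinates: right
# singular vector of the largest singular value, sign-fixed along
# (last - first) point. Independent of the inertia-tensor route.
axis_oracle <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  v <- svd(Xc)$v[, 1]
  if (sum(v * (X[nrow(X), ] - X[1, ])) < 0) v <- -v
  v / sqrt(sum(v^2))
}

# Optimal-superposition RMSD between two conformations of the same atoms
# (Kabsch via SVD), written directly from the definition.
kabsch_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  s <- svd(crossprod(Ac, Bc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((Ac %*% t(R) - Bc)^2)))
}

# Brute-force Rg via the pairwise double sum: Rg^2 = (1/2N^2) sum_ij |ri-rj|^2
rg_pairwise <- function(X) {
  n <- nrow(X)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    s <- s + sum((X[i, ] - X[j, ])^2)
  sqrt(s / (2 * n^2))
}

# Brute-force inertia tensor by direct per-atom summation, then base eigen.
inertia_axis_bruteforce <- function(X) {
  ctr <- colMeans(X)
  I3 <- matrix(0, 3, 3)
  for (i in seq_len(nrow(X))) {
    r <- X[i, ] - ctr
    I3 <- I3 + (sum(r^2) * diag(3) - outer(r, r))
  }
  e <- eigen(I3, symmetric = TRUE)
  v <- e$vectors[, which.min(e$values)]
  if (sum(v * (X[nrow(X), ] - X[1, ])) < 0) v <- -v
  v
}

# Uniformly random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# All pairwise distances of a model's coordinates (rigidity checks).
pairdist <- function(model) as.numeric(dist(coords(model)))

make_test_toy <- function() make_anchored_toy()
make_test_slab <- function() make_membrane_slab()
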