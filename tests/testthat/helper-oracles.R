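# Independent geometry oracles used to cross-check the package's SVD-based
# superposition and rotation algebra. Deliberately implemented by a
# different route (quaternion eigenvector method) than the code under test.

# Horn's closed-form absolute-orientation solution: the optimal rotation is
# the eigenvector with largest eigenvalue of the 4x4 quaternion key matrix.
quaternion_superpose <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  a <- sweep(mobile, 2, cm)
  b <- sweep(target, 2, ct)
  s <- crossprod(a, b)   # S[i,j] = sum a_i b_j
  key <- matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],        s[3,1]-s[1,3],        s[1,2]-s[2,1],
    s[2,3]-s[3,2],        s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],        s[3,1]+s[1,3],
    s[3,1]-s[1,3],        s[1,2]+s[2,1],        s[2,2]-s[1,1]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1],        s[3,1]+s[1,3],        s[2,3]+s[3,2],        s[3,3]-s[1,1]-s[2,2]
  ), 4, 4, byrow = TRUE)
  q <- eigen(key, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  r <- matrix(c(
    1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
    2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
    2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  tvec <- ct - as.numeric(r %*% cm)
  fitted <- sweep(mobile %*% t(r), 2, tvec, "+")
  list(rotation = r, translation = tvec,
       rmsd = sqrt(mean(rowSums((fitted - target)^2))))
}

# Uniform-ish random rotation from a normalized Gaussian quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
    2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
    2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

random_cloud <- function(n, spread = 20) {
  matrix(rnorm(3 * n, sd = spread), ncol = 3)
}

random_frame <- function() {
  p <- random_cloud(3, spread = 10)
  frame_from_markers(p[1, ], p[2, ], p[3, ])
}

frobenius <- function(a, b = 0) norm(as.matrix(a) - b, "F")

# internal coordinate accessor, shared across test files
atom_coords <- headswivel:::atom_coords

# A tiny hand-written three-atom PDB fixture (exact fixed columns).
write_three_atom_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  P     G A  41      10.000  20.000  30.000  1.00 10.00           P",
    "ATOM      2  P     C A 127      11.500  21.500  31.500  1.00 10.00           P",
    "ATOM      3  P     U A 911      -5.250   0.125   7.375  1.00 10.00           P",
    "END"), path)
  path
}
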