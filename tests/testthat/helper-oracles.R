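# Independent oracles used to cross-check implementations.

# Horn's quaternion superposition: optimal rotation/RMSD from the largest
# eigenvalue of the 4x4 key matrix. Independent of the SVD-based Kabsch path.
quaternion_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  cA <- colMeans(A); cB <- colMeans(B)
  Ac <- sweep(A, 2, cA); Bc <- sweep(B, 2, cB)
  S <- crossprod(Bc, Ac)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  lam <- ev$values[1]
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2+x^2-y^2-z^2, 2*(x*y-w*z),     2*(x*z+w*y),
    2*(x*y+w*z),     w^2-x^2+y^2-z^2, 2*(y*z-w*x),
    2*(x*z-w*y),     2*(y*z+w*x),     w^2-x^2-y^2+z^2), 3, 3, byrow = TRUE)
  n <- nrow(A)
  rmsd2 <- (sum(Ac^2) + sum(Bc^2) - 2 * lam) / n
  list(rmsd = sqrt(max(0, rmsd2)), rotation = R)
}

# dense Riemann-sum free energy per bin (brute force)
riemann_pmf <- function(potential, edges, temperature, n_sub = 400) {
  beta <- 1 / (gamdr::kB * temperature)
  nb <- length(edges) - 1
  f <- numeric(nb)
  for (b in seq_len(nb)) {
    xs <- seq(edges[b], edges[b + 1], length.out = n_sub + 1)
    xs <- (xs[-1] + xs[-length(xs)]) / 2
    w <- (edges[b + 1] - edges[b]) / n_sub
    f[b] <- -log(sum(exp(-beta * gamdr::potential_energy(potential, xs))) * w) / beta
  }
  f - min(f)
}

# exact per-bin reweighting estimator by brute-force exponential averaging
exp_average_correction <- function(dV, temperature) {
  beta <- 1 / (gamdr::kB * temperature)
  -log(mean(exp(beta * dV))) / beta
}

# central-difference gradient of a scalar function of an n x 3 matrix
numerical_gradient <- function(f, coords, h = 1e-6) {
  g <- coords * 0
  for (i in seq_len(nrow(coords))) {
    for (k in 1:3) {
      cp <- coords; cm <- coords
      cp[i, k] <- cp[i, k] + h
      cm[i, k] <- cm[i, k] - h
      g[i, k] <- (f(cp) - f(cm)) / (2 * h)
    }
  }
  g
}

rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
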