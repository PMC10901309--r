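# Exact-enumeration Mann-Whitney oracle (no ties): two-sided p from the
# full permutation null of U over all group assignments.
mwu_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  n_a <- length(a); n_b <- length(b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  splits <- utils::combn(n_a + n_b, n_a)
  us <- colSums(matrix(rk[splits], nrow = n_a)) - n_a * (n_a + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# A random convex quadrilateral with vertices in traversal order: points on
# the unit circle in angular order, pushed through a random invertible
# affine map (affine maps preserve convexity and vertex order).
random_convex_quad <- function() {
  ang <- sort(stats::runif(4, 0, 2 * pi))
  if (min(diff(ang)) < 1e-3) ang <- ang + cumsum(rep(0.01, 4))
  pts <- cbind(cos(ang), sin(ang))
  repeat {
    A <- matrix(stats::rnorm(4, sd = 1), 2, 2)
    if (abs(det(A)) > 0.1) break
  }
  sweep(pts %*% A, 2, stats::rnorm(2), "+")
}
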