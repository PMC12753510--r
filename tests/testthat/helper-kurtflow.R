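# shared fixtures, built in code

# compact three-shell scheme for fast fitting tests
small_scheme <- function() {
  default_scheme(n_b0 = 3, n_inner = 24, n_outer = 36)
}

# random plausible axisymmetric DKI parameter set
rand_axisym <- function() {
  rd <- runif(1, 0.3, 0.9)
  ad <- rd + runif(1, 0.1, 1.0)
  axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
  list(ad = ad, rd = rd, ak = runif(1, 0.4, 1.2), rk = runif(1, 0.6, 1.8),
       mk = runif(1, 0.7, 1.3), axis = axis)
}

# random unconstrained (but fittable) tensor pair
rand_tensors <- function() {
  A <- matrix(rnorm(9, sd = 0.4), 3, 3)
  D <- crossprod(A) + 0.3 * diag(3)            # SPD, ~0.3-1.5 um^2/ms scale
  w15 <- rnorm(15, sd = 0.15)
  list(d6 = matrix_to_d6_(D), w15 = w15)
}

matrix_to_d6_ <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

# independent symbolic evaluation of the DKI exponent by explicit loops
# over all tensor indices (oracle, never shares code with the package)
oracle_dki_signal <- function(s0, d6, w15, bval, bvec) {
  D <- matrix(c(d6[1], d6[4], d6[5],
                d6[4], d6[2], d6[6],
                d6[5], d6[6], d6[3]), 3, 3)
  # rebuild the full symmetric W by brute force
  idx <- list(c(1,1,1,1), c(2,2,2,2), c(3,3,3,3), c(1,1,1,2), c(1,1,1,3),
              c(1,2,2,2), c(2,2,2,3), c(1,3,3,3), c(2,3,3,3), c(1,1,2,2),
              c(1,1,3,3), c(2,2,3,3), c(1,1,2,3), c(1,2,2,3), c(1,2,3,3))
  W <- array(0, c(3, 3, 3, 3))
  for (u in seq_along(idx)) {
    perm <- unique(t(apply(expand.grid(1:4, 1:4, 1:4, 1:4), 1, function(p) {
      if (length(unique(p)) == 4) idx[[u]][unlist(p)] else rep(NA, 4)
    })))
    perm <- perm[stats::complete.cases(perm), , drop = FALSE]
    for (r in seq_len(nrow(perm)))
      W[perm[r, 1], perm[r, 2], perm[r, 3], perm[r, 4]] <- w15[u]
  }
  md <- sum(diag(D)) / 3
  vapply(seq_along(bval), function(v) {
    n <- bvec[v, ]
    b <- bval[v] / 1000
    dn <- as.numeric(t(n) %*% D %*% n)
    wn <- 0
    for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3)
      wn <- wn + W[i, j, k, l] * n[i] * n[j] * n[k] * n[l]
    s0 * exp(-b * dn + b^2 / 6 * md^2 * wn)
  }, numeric(1))
}

# direct per-voxel averaging oracle for ROI extraction
oracle_roi_mean <- function(metric, include, exclude) {
  eff <- include
  for (ex in exclude) eff <- eff & !ex
  v <- metric[eff]
  v <- v[is.finite(v)]
  c(mean = mean(v), sd = stats::sd(v), n = length(v))
}
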