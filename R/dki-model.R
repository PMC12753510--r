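# DKI forward model: tensors, directional contractions, signal prediction.
#
# Unit conventions (the field's display units):
#   diffusivities in um^2/ms  (numerically identical to 1e-3 mm^2/s)
#   b-values stored in s/mm^2 (FSL convention) and converted to ms/um^2
#   internally, so b * D is dimensionless.

# unique index sets of the fully symmetric kurtosis tensor and their
# multinomial multiplicities; order fixed package-wide
.w15_idx <- matrix(c(
  1, 1, 1, 1,
  2, 2, 2, 2,
  3, 3, 3, 3,
  1, 1, 1, 2,
  1, 1, 1, 3,
  1, 2, 2, 2,
  2, 2, 2, 3,
  1, 3, 3, 3,
  2, 3, 3, 3,
  1, 1, 2, 2,
  1, 1, 3, 3,
  2, 2, 3, 3,
  1, 1, 2, 3,
  1, 2, 2, 3,
  1, 2, 3, 3), ncol = 4, byrow = TRUE)

.w15_mult <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)

#' Directional design matrix for the diffusion tensor
#'
#' Row i gives the monomials such that `d_design(n) %*% d6` equals
#' \eqn{n^T D n} for the 6-component tensor `d6` ordered
#' (xx, yy, zz, xy, xz, yz).
#'
#' @param dirs numeric matrix, one unit direction per row.
#' @return matrix with 6 columns.
#' @keywords internal
d_design <- function(dirs) {
  dirs <- rbind(dirs)
  cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
        2 * dirs[, 1] * dirs[, 2],
        2 * dirs[, 1] * dirs[, 3],
        2 * dirs[, 2] * dirs[, 3])
}

#' Directional design matrix for the kurtosis tensor
#'
#' Row i gives multiplicity-weighted quartic monomials such that
#' `w_design(n) %*% w15` equals \eqn{W(n) = \sum_{ijkl} W_{ijkl} n_i n_j n_k n_l}.
#'
#' @param dirs numeric matrix, one unit direction per row.
#' @return matrix with 15 columns.
#' @keywords internal
w_design <- function(dirs) {
  dirs <- rbind(dirs)
  out <- matrix(0, nrow(dirs), 15)
  for (j in seq_len(15)) {
    id <- .w15_idx[j, ]
    out[, j] <- .w15_mult[j] *
      dirs[, id[1]] * dirs[, id[2]] * dirs[, id[3]] * dirs[, id[4]]
  }
  out
}

d6_to_matrix <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

matrix_to_d6 <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

# expand the 15 unique components into the full 3x3x3x3 symmetric array
w15_to_full <- function(w15) {
  W <- array(0, c(3, 3, 3, 3))
  for (j in seq_len(15)) {
    id <- .w15_idx[j, ]
    perms <- unique(perms4(id))
    for (p in seq_len(nrow(perms))) {
      q <- perms[p, ]
      W[q[1], q[2], q[3], q[4]] <- w15[j]
    }
  }
  W
}

full_to_w15 <- function(W) {
  vapply(seq_len(15), function(j) {
    id <- .w15_idx[j, ]
    W[id[1], id[2], id[3], id[4]]
  }, numeric(1))
}

# all permutations of a length-4 index vector (with duplicates)
perms4 <- function(x) {
  p <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  matrix(x[p], ncol = 4)
}

#' Rotate a kurtosis tensor
#'
#' Applies the same rotation to all four slots of the fully symmetric
#' fourth-order tensor.
#'
#' @param w15 the 15 unique components.
#' @param R a 3x3 rotation matrix (new = R %*% old coordinates).
#' @return rotated 15-vector.
#' @keywords internal
rotate_w15 <- function(w15, R) {
  W <- w15_to_full(w15)
  grid <- as.matrix(expand.grid(i = 1:3, j = 1:3, k = 1:3, l = 1:3))
  wflat <- W[grid]
  vapply(seq_len(15), function(u) {
    id <- .w15_idx[u, ]
    sum(R[id[1], grid[, 1]] * R[id[2], grid[, 2]] *
        R[id[3], grid[, 3]] * R[id[4], grid[, 4]] * wflat)
  }, numeric(1))
}

rotate_d6 <- function(d6, R) {
  matrix_to_d6(R %*% d6_to_matrix(d6) %*% t(R))
}

#' Deterministic uniform sphere sample
#'
#' Fibonacci-spiral point set used for directional averaging of apparent
#' kurtosis and for synthetic gradient shells.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  key <- as.character(n)
  hit <- .fib_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  out <- unname(cbind(r * cos(phi), r * sin(phi), z))
  .fib_cache[[key]] <- out
  out
}

.fib_cache <- new.env(parent = emptyenv())

#' Diffusion acquisition scheme
#'
#' @param bval numeric vector of b-values in s/mm^2.
#' @param bvec matrix of gradient unit vectors, one row per volume
#'   (rows for b = 0 volumes may be zero).
#' @param max_b maximum allowed b-value (protocol envelope).
#' @return an `acquisition_scheme` object.
#' @export
acquisition_scheme <- function(bval, bvec, max_b = 2500) {
  bvec <- rbind(bvec)
  stopifnot(length(bval) == nrow(bvec), ncol(bvec) == 3)
  if (any(bval < 0)) stop("negative b-values")
  if (max(bval) > max_b) stop("b-values exceed the protocol maximum of ", max_b)
  nz <- bval > 0
  if (!any(!nz)) stop("scheme needs at least one b = 0 volume")
  nrm <- sqrt(rowSums(bvec[nz, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("gradient directions must be unit norm")
  shells <- sort(unique(bval[nz]))
  if (length(shells) < 2)
    stop("scheme is not identifiable: at least 2 nonzero shells required")
  outer_dirs <- unique(round(bvec[bval == max(shells), , drop = FALSE], 8))
  if (nrow(outer_dirs) < 15)
    stop("scheme is not identifiable: < 15 distinct outer-shell directions")
  structure(list(bval = as.numeric(bval), bvec = bvec,
                 n_b0 = sum(!nz), shells = shells),
            class = "acquisition_scheme")
}

#' Default synthetic three-shell scheme
#'
#' A desk-scale stand-in for a dense 201-direction 0-2500 s/mm^2 protocol:
#' 6 b = 0 volumes plus Fibonacci-sphere shells at b = 1000 (30 directions)
#' and b = 2500 s/mm^2 (60 directions).
#'
#' @param n_b0,n_inner,n_outer volume counts per shell.
#' @param b_inner,b_outer shell b-values in s/mm^2.
#' @return an `acquisition_scheme`.
#' @export
default_scheme <- function(n_b0 = 6, n_inner = 30, n_outer = 60,
                           b_inner = 1000, b_outer = 2500) {
  bval <- c(rep(0, n_b0), rep(b_inner, n_inner), rep(b_outer, n_outer))
  bvec <- rbind(matrix(0, n_b0, 3),
                fibonacci_sphere(n_inner),
                fibonacci_sphere(n_outer))
  acquisition_scheme(bval, bvec)
}

#' Predict DKI signals
#'
#' Evaluates the standard kurtosis signal equation
#' \deqn{\ln S = \ln S_0 - b D(n) + \frac{b^2}{6} \bar{MD}^2 W(n)}
#' with \eqn{D(n) = n^T D n} and \eqn{W(n)} the quartic contraction of the
#' kurtosis tensor.
#'
#' @param s0 signal at b = 0.
#' @param d6 diffusion tensor (6 unique components, um^2/ms).
#' @param w15 kurtosis tensor (15 unique components, unitless).
#' @param scheme an [acquisition_scheme()].
#' @return numeric vector of signals, one per scheme volume.
#' @export
predict_dki_signal <- function(s0, d6, w15, scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"), s0 > 0)
  bb <- scheme$bval / 1000                # ms/um^2
  dn <- as.vector(d_design(scheme$bvec) %*% d6)
  wn <- as.vector(w_design(scheme$bvec) %*% w15)
  md <- sum(d6[1:3]) / 3
  as.vector(s0 * exp(-bb * dn + bb^2 / 6 * md^2 * wn))
}

#' Apparent diffusivity and kurtosis along a direction
#'
#' @param d6 diffusion tensor components.
#' @param w15 kurtosis tensor components.
#' @param direction unit vector.
#' @param tol directions with D(n) below this are flagged non-evaluable.
#' @return list with `d` (um^2/ms), `k` (unitless) and `evaluable`.
#' @export
apparent_along <- function(d6, w15, direction, tol = 1e-9) {
  direction <- as.numeric(direction)
  if (abs(sum(direction^2) - 1) > 1e-6) stop("direction must be unit norm")
  dn <- as.vector(d_design(direction) %*% d6)
  if (dn < tol)
    return(list(d = dn, k = NA_real_, evaluable = FALSE))
  wn <- as.vector(w_design(direction) %*% w15)
  md <- sum(d6[1:3]) / 3
  list(d = dn, k = md^2 / dn^2 * wn, evaluable = TRUE)
}

#' Build an axisymmetric DKI ground truth
#'
#' Constructs diffusion and kurtosis tensors that reproduce the requested
#' axial/radial diffusivities and axial/radial/mean kurtosis exactly under
#' the package's directional-averaging convention (Fibonacci sphere sample
#' anchored to the diffusion eigenframe, see [dki_metrics()]).
#'
#' @param ad,rd axial and radial diffusivity (um^2/ms), `ad >= rd >= 0`.
#' @param ak,rk,mk axial, radial and mean kurtosis targets (unitless).
#' @param axis principal axis (need not be normalized).
#' @param sphere_n sphere sample size defining the mean-kurtosis convention.
#' @return list with elements `d6` and `w15`.
#' @export
axisymmetric_dki <- function(ad, rd, ak, rk, mk, axis = c(0, 0, 1),
                             sphere_n = 1000) {
  stopifnot(ad >= rd, rd >= 0)
  v <- axis / sqrt(sum(axis^2))
  md <- (ad + 2 * rd) / 3
  wpar <- ak * ad^2 / md^2
  wperp <- rk * rd^2 / md^2
  # mean kurtosis over the eigenframe sphere sample fixes the mixed term
  f <- fibonacci_sphere(sphere_n)
  c2 <- f[, 1]^2                       # cos^2(theta to principal axis)
  s2 <- 1 - c2
  dn <- ad * c2 + rd * s2
  g <- md^2 / dn^2
  base <- mean(g * (wpar * c2^2 + wperp * s2^2))
  cross <- mean(g * 6 * c2 * s2)
  wm <- (mk - base) / cross
  # local frame: (p, q, v) with v the symmetry axis (local z)
  e <- diag(3)[, which.min(abs(v))]
  p <- e - sum(e * v) * v
  p <- p / sqrt(sum(p^2))
  q <- c(v[2] * p[3] - v[3] * p[2],
         v[3] * p[1] - v[1] * p[3],
         v[1] * p[2] - v[2] * p[1])
  R <- cbind(p, q, v)
  w15_local <- numeric(15)
  w15_local[c(1, 2)] <- wperp          # W1111, W2222
  w15_local[3] <- wpar                 # W3333
  w15_local[10] <- wperp / 3           # W1122 (in-plane isotropy)
  w15_local[c(11, 12)] <- wm           # W1133, W2233
  d6 <- matrix_to_d6(rd * diag(3) + (ad - rd) * tcrossprod(v))
  list(d6 = d6, w15 = rotate_w15(w15_local, R))
}
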