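#' Closed-form least-squares rigid registration of paired point sets
#'
#' Finds the rotation R (det = +1) and translation t minimising
#' `sum_i || R a_i + t - b_i ||^2` via centroid demeaning and SVD of the
#' cross-covariance (the Kabsch/Horn solution). Reflections are never
#' returned: the smallest singular direction is sign-corrected.
#'
#' @param a,b n x 3 matrices of corresponding points (a maps onto b), n >= 3,
#'   not collinear.
#' @return list with `transform` (a [rigid_transform()] mapping a onto b),
#'   `rotation` (3x3 matrix) and `residual_rms` (mm).
#' @export
kabsch_fit <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L || nrow(a) < 3L)
    abort_qa("kabsch_fit needs two equal n x 3 point sets with n >= 3")
  ca <- colMeans(a); cb <- colMeans(b)
  ac <- sweep(a, 2, ca); bc <- sweep(b, 2, cb)
  sv_a <- svd(ac)$d
  if (sv_a[2] < 1e-9 * max(sv_a[1], 1))
    abort_qa("degenerate (collinear) point configuration; cannot register")
  h <- crossprod(ac, bc)                 # sum a_i b_i^T
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - drop(r %*% ca)
  resid <- sweep(a %*% t(r), 2, t, `+`) - b
  rms <- sqrt(mean(rowSums(resid^2)))
  list(transform = rigid_from_matrix(r, t), rotation = r, residual_rms = rms)
}
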