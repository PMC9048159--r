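#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_qa <- function(msg, class = "petmrqa_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Otsu threshold of a numeric vector
#'
#' Maximises between-class variance over a fixed-bin histogram. Used to
#' separate bright phantom structures from background before connected
#' component analysis.
#'
#' @param x numeric vector (or array) of intensities.
#' @param n_bins number of histogram bins.
#' @return threshold value on the scale of `x`.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (!length(x)) abort_qa("otsu_threshold: no finite values")
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  # between-class variance for every cut
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  mids[which.max(bcv)]
}

# 6-connected neighbour offsets in linear index space for an nx x ny x nz array
neighbour_offsets6 <- function(dm) {
  nx <- dm[1]; ny <- dm[2]
  c(-1L, 1L, -nx, nx, -nx * ny, nx * ny)
}

#' Label connected components of a 3-D logical mask
#'
#' 6-connectivity flood fill. Returns an integer array of the same dimensions
#' with 0 for background and 1..k component labels, ordered by decreasing size.
#'
#' @param mask 3-D logical array.
#' @return integer array of labels with attribute `sizes` (voxels/component).
#' @export
label_components3d <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  dm <- dim(mask)
  n <- length(mask)
  lab <- integer(n)
  offs <- neighbour_offsets6(dm)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  seeds <- which(mask)
  cur <- 0L
  sizes <- integer(0)
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    count <- 1L
    while (length(queue)) {
      # expand whole frontier at once
      i0 <- queue - 1L
      ix <- i0 %% nx
      iy <- (i0 %/% nx) %% ny
      iz <- i0 %/% (nx * ny)
      nxt <- integer(0)
      for (d in seq_along(offs)) {
        ok <- switch(d,
          ix > 0L, ix < nx - 1L, iy > 0L, iy < ny - 1L, iz > 0L, iz < nz - 1L)
        cand <- queue[ok] + offs[d]
        cand <- cand[mask[cand] & lab[cand] == 0L]
        if (length(cand)) {
          lab[cand] <- cur
          nxt <- c(nxt, cand)
        }
      }
      queue <- nxt
      count <- count + length(queue)
    }
    sizes <- c(sizes, count)
  }
  # relabel by decreasing size
  if (cur > 1L) {
    ord <- order(sizes, decreasing = TRUE)
    remap <- integer(cur)
    remap[ord] <- seq_len(cur)
    nzv <- lab != 0L
    lab[nzv] <- remap[lab[nzv]]
    sizes <- sizes[ord]
  }
  dim(lab) <- dm
  attr(lab, "sizes") <- sizes
  lab
}

#' Erode a 3-D logical mask by one voxel (6-connectivity)
#' @param mask 3-D logical array.
#' @return eroded logical array.
#' @export
erode3d <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  dm <- dim(mask)
  out <- mask
  shift <- function(m, axis, by) {
    res <- array(FALSE, dm)
    idx_src <- lapply(dm, seq_len)
    idx_dst <- idx_src
    n <- dm[axis]
    if (by > 0) { idx_dst[[axis]] <- seq(1 + by, n); idx_src[[axis]] <- seq(1, n - by) }
    else        { idx_dst[[axis]] <- seq(1, n + by); idx_src[[axis]] <- seq(1 - by, n) }
    res[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    res
  }
  for (axis in 1:3) for (by in c(-1L, 1L)) out <- out & shift(mask, axis, by)
  out
}

#' Add Rician noise to a noiseless magnitude image
#'
#' MR magnitude images have Rician-distributed noise: the magnitude of a
#' complex signal with independent Gaussian noise of standard deviation
#' `sigma` on each channel. At low SNR this biases the mean upwards.
#'
#' @param x numeric array of noiseless signal magnitudes.
#' @param sigma Gaussian channel noise SD.
#' @return array of noisy magnitudes, same shape.
#' @export
add_rician_noise <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- length(x)
  sqrt((x + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

# analytic mean of a Rician distribution (used in tests/vignette)
#' Mean of the Rician distribution
#' @param nu underlying signal magnitude.
#' @param sigma channel noise SD.
#' @return expected magnitude.
#' @export
rician_mean <- function(nu, sigma) {
  x <- -nu^2 / (2 * sigma^2)
  # Laguerre half polynomial via Bessel functions
  l_half <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) - x * besselI(-x / 2, 1))
  sigma * sqrt(pi / 2) * l_half
}
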