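# Separable truncated-Gaussian convolution, implemented as banded matrix
# products along one axis at a time. Sizes here (<= a few hundred pixels per
# axis) make the dense operator cheap and keep the boundary handling explicit.

# normalized 1D Gaussian kernel truncated at `radius` pixels
gaussian_kernel_1d <- function(sigma, radius) {
  stopifnot(sigma > 0, radius >= 0)
  t <- seq.int(-radius, radius)
  w <- exp(-t^2 / (2 * sigma^2))
  w / sum(w)
}

# n x n convolution operator for `kernel` with replicate ("clamp") or zero
# boundary; out[i] = sum_t kernel[t] * in[clamp(i + t)]
conv_operator <- function(n, kernel, boundary = c("replicate", "zero")) {
  boundary <- match.arg(boundary)
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  # column i of K accumulates the (clamped) source weights of output i,
  # so that (row-vector %*% K)[i] = sum_t w[t] * in[clamp(i + t)]
  for (t in seq.int(-r, r)) {
    j <- seq_len(n) + t
    if (boundary == "replicate") j <- pmin(pmax(j, 1L), n)
    keep <- j >= 1L & j <= n
    idx <- cbind(j[keep], which(keep))
    K[idx] <- K[idx] + kernel[t + r + 1L]
  }
  K
}

# convolve a 3D (z, y, x) array along one axis
convolve_axis <- function(arr, kernel, axis, boundary = "replicate") {
  d <- dim(arr)
  perm <- switch(axis, z = c(2L, 3L, 1L), y = c(1L, 3L, 2L), x = c(1L, 2L, 3L))
  a <- aperm(arr, perm)
  da <- dim(a)
  K <- conv_operator(da[3], kernel, boundary)
  m <- matrix(a, ncol = da[3]) %*% K
  a <- array(m, da)
  aperm(a, order(perm))
}

# per-plane (y, x) Gaussian blur of a 3D stack
gauss_blur_planes <- function(arr, sigma, radius, boundary = "replicate") {
  k <- gaussian_kernel_1d(sigma, radius)
  convolve_axis(convolve_axis(arr, k, "y", boundary), k, "x", boundary)
}

# anisotropic 3D Gaussian blur with per-axis sigma (z, y, x)
gauss_blur_3d <- function(arr, sigma_zyx, radius_zyx = ceiling(3 * sigma_zyx),
                          boundary = "replicate") {
  out <- arr
  for (i in 1:3) {
    ax <- c("z", "y", "x")[i]
    if (dim(arr)[i] > 1L && sigma_zyx[i] > 0) {
      k <- gaussian_kernel_1d(sigma_zyx[i], radius_zyx[i])
      out <- convolve_axis(out, k, ax, boundary)
    }
  }
  out
}
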